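# Synthetic genomes with planted, structurally faithful TE copies plus truth
# tables, simulated reads, transcript coverage and peptides. The generator is
# the test-bed for every downstream stage: all parameters are deterministic
# given a seed.

#' A transposable-element template for the synthetic generator
#'
#' Describes the terminal structure (identical LTRs, reverse-complement TIRs,
#' poly-A tail), target-site-duplication length, encoded protein domains and
#' total length of a family to be planted.
#'
#' @slot family_id family name
#' @slot superfamily one of Copia, Gypsy, L1, hAT, Mariner/Tc1, Harbinger,
#'   PiggyBac, or "none" for MITE/SINE/TRIM/LARD templates
#' @slot order TE order the template realizes
#' @slot wicker_class "I" or "II"
#' @slot ltr_len,tir_len terminal repeat length in bp (NA when absent)
#' @slot tsd_len target-site duplication length sampled at insertion
#' @slot orf_domains ordered domain tokens from RT, INT, EN, TASE
#' @slot total_len total element length in bp
#' @slot tail poly-A tail length (NA when absent)
#' @export
setClass("TETemplate", representation(
  family_id = "character", superfamily = "character", order = "character",
  wicker_class = "character", ltr_len = "integer", tir_len = "integer",
  tsd_len = "integer", orf_domains = "character", total_len = "integer",
  tail = "integer"))

setValidity("TETemplate", function(object) {
  if (!is.na(object@ltr_len) && !is.na(object@tir_len))
    return("a template cannot have both LTRs and TIRs")
  if (!is.na(object@ltr_len) && object@ltr_len < 100L)
    return("LTR-type templates need ltr_len >= 100")
  if (object@order %in% c("MITE", "SINE", "TRIM", "LARD") &&
      length(object@orf_domains) > 0)
    return("non-autonomous structural templates must have no ORF domains")
  if (object@total_len < 50L) return("total_len too small")
  if (length(object@orf_domains) &&
      !all(object@orf_domains %in% c("RT", "INT", "EN", "TASE")))
    return("unknown domain token")
  TRUE
})

#' @rdname TETemplate-class
#' @param family_id,superfamily,order,wicker_class,ltr_len,tir_len,tsd_len,orf_domains,total_len,tail
#'   see slots
#' @export
teTemplate <- function(family_id, superfamily, order, wicker_class,
                       total_len, tsd_len, ltr_len = NA_integer_,
                       tir_len = NA_integer_, orf_domains = character(0),
                       tail = NA_integer_) {
  new("TETemplate", family_id = family_id, superfamily = superfamily,
      order = order, wicker_class = wicker_class,
      ltr_len = as.integer(ltr_len), tir_len = as.integer(tir_len),
      tsd_len = as.integer(tsd_len), orf_domains = orf_domains,
      total_len = as.integer(total_len), tail = as.integer(tail))
}

#' The built-in template catalogue (the study conditions)
#'
#' Ten families spanning the classifiable orders: seven autonomous (Copia,
#' Gypsy, L1, hAT, Mariner, Harbinger, PiggyBac) and three structural
#' non-autonomous (MITE, SINE, TRIM). Lengths and terminal structures follow
#' the field's conventional ranges for each superfamily.
#'
#' @param include_lard also include a LARD template (off by default)
#' @return named list of \linkS4class{TETemplate}
#' @export
teTemplateCatalog <- function(include_lard = FALSE) {
  tl <- list(
    teTemplate("copia1",    "Copia",       "LTR",  "I",  4200L, 5L, ltr_len = 200L,
               orf_domains = c("RT", "INT")),
    teTemplate("gypsy1",    "Gypsy",       "LTR",  "I",  5200L, 4L, ltr_len = 300L,
               orf_domains = c("INT", "RT")),
    teTemplate("line1",     "L1",          "LINE", "I",  4000L, 8L,
               orf_domains = c("EN", "RT"), tail = 16L),
    teTemplate("hat1",      "hAT",         "TIR",  "II", 3000L, 8L, tir_len = 15L,
               orf_domains = "TASE"),
    teTemplate("mariner1",  "Mariner/Tc1", "TIR",  "II", 1600L, 2L, tir_len = 30L,
               orf_domains = "TASE"),
    teTemplate("harbinger1","Harbinger",   "TIR",  "II", 2600L, 3L, tir_len = 25L,
               orf_domains = "TASE"),
    teTemplate("piggybac1", "PiggyBac",    "TIR",  "II", 2400L, 4L, tir_len = 13L,
               orf_domains = "TASE"),
    teTemplate("mite1",     "none",        "MITE", "II",  400L, 2L, tir_len = 30L),
    teTemplate("sine1",     "none",        "SINE", "I",   250L, 8L, tail = 12L),
    teTemplate("trim1",     "none",        "TRIM", "I",   900L, 5L, ltr_len = 120L))
  if (include_lard)
    tl <- c(tl, list(teTemplate("lard1", "none", "LARD", "I", 5500L, 5L,
                                ltr_len = 200L)))
  names(tl) <- vapply(tl, function(t) t@family_id, character(1))
  tl
}

# Family-specific variable peptide (60 aa) inside the transposase/polyprotein
# ORF; deterministic per (family, seed). Peptide evidence is drawn from here
# so that it resolves families (the shared domain consensi do not).
.familyVarAA <- function(family_id, seed) {
  h <- sum(utf8ToInt(family_id) * seq_len(nchar(family_id)))
  withSeed((as.integer(seed) * 131L + h) %% 2147483647L,
           paste(sample(.AA20, 60, replace = TRUE), collapse = ""))
}

#' Realize a template as a concrete DNA sequence
#'
#' LTR-type templates get identical direct terminal repeats; TIR types get
#' reverse-complement termini; L1/SINE get a poly-A tail. Each requested
#' domain token is embedded, in order, as an in-frame reverse-translated copy
#' of its consensus peptide inside a single long ORF, followed by a
#' family-specific variable peptide. Deterministic given the seed.
#'
#' @param template a \linkS4class{TETemplate}
#' @param seed integer seed
#' @return list with elements \code{seq} (DNAString), \code{id},
#'   \code{orf_range} (nt range of the ORF or NULL), \code{orf_aa},
#'   \code{var_aa}, and \code{template}
#' @export
makeTemplateSequence <- function(template, seed) {
  t <- template
  peps <- domainPeptides()
  withSeed(seed, {
    orf_nt <- ""
    orf_aa <- ""
    var_aa <- ""
    if (length(t@orf_domains) > 0) {
      var_aa <- .familyVarAA(t@family_id, seed)
      linker <- "GAETWKQVHS"   # non-repetitive spacer between domains
      orf_aa <- paste0(paste(peps[t@orf_domains], collapse = linker),
                       linker, var_aa)
      orf_nt <- paste0("ATG", reverseTranslate(orf_aa), "TAA")
    }
    term_len <- if (!is.na(t@ltr_len)) 2L * t@ltr_len else
      if (!is.na(t@tir_len)) 2L * t@tir_len else 0L
    tail_len <- if (!is.na(t@tail)) t@tail else 0L
    internal <- t@total_len - term_len - tail_len - nchar(orf_nt)
    if (internal < 20L)
      .stopf("template '%s': total_len %d too small for its structure",
             t@family_id, t@total_len)
    left_pad <- internal %/% 2L
    right_pad <- internal - left_pad
    build <- function() {
      mid <- paste0(randDNA(left_pad), orf_nt, randDNA(right_pad))
      body <- if (!is.na(t@ltr_len)) {
        ltr <- randDNA(t@ltr_len)
        paste0(ltr, mid, ltr)
      } else if (!is.na(t@tir_len)) {
        tir <- randDNA(t@tir_len)
        paste0(tir, mid, rcChar(tir))
      } else mid
      if (tail_len > 0L) paste0(body, strrep("A", tail_len)) else body
    }
    s <- build()
    if (length(t@orf_domains) == 0L && t@total_len >= 300L) {
      # non-coding templates must stay non-coding: redraw until no ORF >= 300 bp
      tries <- 0L
      while (nrow(findORFs(s, 300L)) > 0L && tries < 100L) {
        s <- build(); tries <- tries + 1L
      }
      if (nrow(findORFs(s, 300L)) > 0L)
        .stopf("template '%s': could not draw an ORF-free realization", t@family_id)
    }
    list(seq = DNAString(s), id = t@family_id,
         orf_range = if (nchar(orf_nt)) {
           st <- if (!is.na(t@ltr_len)) t@ltr_len + left_pad + 1L
                 else if (!is.na(t@tir_len)) t@tir_len + left_pad + 1L
                 else left_pad + 1L
           c(st, st + nchar(orf_nt) - 1L)
         } else NULL,
         orf_aa = orf_aa, var_aa = var_aa, template = t)
  })
}

#' Realize a whole catalogue deterministically
#'
#' @param templates list of TETemplate
#' @param seed integer; each family uses a seed derived from \code{seed} and
#'   its family id, so any subset of a catalogue realizes identically
#' @return named list of makeTemplateSequence() results
#' @export
templateSequences <- function(templates, seed) {
  out <- lapply(templates, function(t) {
    h <- sum(utf8ToInt(t@family_id) * seq_len(nchar(t@family_id)))
    makeTemplateSequence(t, (as.integer(seed) * 1009L + h) %% 2147483647L)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' The synthetic reference databank
#'
#' One exemplar sequence per template family, named with Wicker-coded
#' headers, packaged as a classified \linkS4class{TELibrary}. Serves as the
#' nucleotide databank for similarity detection and classification, and as
#' the reference family library for coverage-score benchmarking.
#'
#' @param templates list of TETemplate (default: the built-in catalogue)
#' @param seed integer seed (must match the seed used to plant copies if the
#'   databank should contain the planted families)
#' @return a TELibrary named "databank"
#' @export
referenceDatabank <- function(templates = teTemplateCatalog(), seed = 1L) {
  ts <- templateSequences(templates, seed)
  seqs <- DNAStringSet(lapply(ts, `[[`, "seq"))
  tmpl <- lapply(ts, `[[`, "template")
  ids <- vapply(tmpl, function(t)
    paste0(wickerCode(t@order, t@superfamily), "_", t@family_id), character(1))
  names(seqs) <- ids
  cls <- DataFrame(
    wicker_class = vapply(tmpl, function(t) t@wicker_class, character(1)),
    order = vapply(tmpl, function(t) t@order, character(1)),
    superfamily = vapply(tmpl, function(t)
      if (t@superfamily == "none") "none" else t@superfamily, character(1)),
    autonomy = vapply(tmpl, function(t)
      if (t@order %in% c("MITE", "SINE", "TRIM", "LARD")) "non_autonomous"
      else "autonomous", character(1)),
    family_id = vapply(tmpl, function(t) t@family_id, character(1)))
  TELibrary("databank", seqs, cls)
}

#' Plant TE copies into a random background genome
#'
#' The background is i.i.d. uniform ACGT. Each copy is inserted at a drawn
#' position with a freshly sampled target-site duplication on both flanks,
#' mutated at the requested divergence, optionally truncated to a uniform
#' 20--60\% prefix (fragmentation), and placed on a random strand. Truth
#' intervals are exact element spans (TSDs immediately outside).
#'
#' @param background_len total background length in bp
#' @param templates list of TETemplate
#' @param copies_per_family integer (recycled over families)
#' @param divergence per-base point-mutation rate applied to each copy
#' @param frag_prob probability that a copy is truncated
#' @param seed integer seed (drives background, positions, TSDs, mutations)
#' @param n_contigs split the background over this many contigs
#' @param min_gap minimum spacing between insertion points (bp)
#' @return list(genome = named DNAStringSet, truth = GRanges with mcols
#'   family_id, superfamily, order, completeness, divergence, tsd)
#' @export
plantCopies <- function(background_len, templates, copies_per_family,
                        divergence = 0, frag_prob = 0, seed = 1L,
                        n_contigs = 1L, min_gap = 300L) {
  tseqs <- templateSequences(templates, seed)
  ncop <- rep(as.integer(copies_per_family), length.out = length(templates))
  planted_bp <- sum(vapply(seq_along(tseqs), function(i)
    length(tseqs[[i]]$seq) * ncop[i], numeric(1)))
  if (planted_bp > 0.5 * background_len)
    .stopf("capacity error: %d bp of copies exceeds half of the %d bp background",
           planted_bp, background_len)
  withSeed(as.integer(seed) + 7L, {
    cw <- rep(background_len %/% n_contigs, n_contigs)
    cw[n_contigs] <- cw[n_contigs] + background_len %% n_contigs
    contig_names <- paste0("contig", seq_len(n_contigs))
    bg <- lapply(cw, randDNA)
    names(bg) <- contig_names
    ## plan insertions
    ins <- list()
    points <- lapply(seq_len(n_contigs), function(i) integer(0))
    for (i in seq_along(tseqs)) {
      tmpl <- tseqs[[i]]$template
      full <- as.character(tseqs[[i]]$seq)
      for (j in seq_len(ncop[i])) {
        cp <- full
        completeness <- 1
        if (frag_prob > 0 && runif(1) < frag_prob) {
          completeness <- runif(1, 0.2, 0.6)
          cp <- substr(cp, 1, max(50L, floor(nchar(cp) * completeness)))
          completeness <- nchar(cp) / nchar(full)
        }
        if (divergence > 0) {
          hit <- which(runif(nchar(cp)) < divergence)
          if (length(hit)) {
            ch <- strsplit(cp, "", fixed = TRUE)[[1]]
            for (p in hit)
              ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
            cp <- paste(ch, collapse = "")
          }
        }
        st <- sample(c("+", "-"), 1)
        placed <- if (st == "-") rcChar(cp) else cp
        tsd <- randDNA(tmpl@tsd_len)
        ## draw a position
        ok <- FALSE
        for (try in 1:500) {
          ct <- sample.int(n_contigs, 1, prob = cw)
          pos <- sample.int(max(1L, cw[ct] - 2L * min_gap), 1) + min_gap
          if (all(abs(points[[ct]] - pos) >= min_gap + nchar(placed))) { ok <- TRUE; break }
        }
        if (!ok) .stopf("capacity error: could not place copy %d of '%s'",
                        j, tmpl@family_id)
        points[[ct]] <- c(points[[ct]], pos)
        ins[[length(ins) + 1L]] <- list(
          contig = ct, pos = pos, seq = placed, tsd = tsd, strand = st,
          family_id = tmpl@family_id,
          superfamily = if (tmpl@superfamily == "none") "none" else tmpl@superfamily,
          order = tmpl@order, completeness = completeness)
      }
    }
    ## splice insertions into each contig, computing truth coordinates
    truth <- list()
    genome <- character(n_contigs)
    for (ct in seq_len(n_contigs)) {
      my <- Filter(function(x) x$contig == ct, ins)
      if (length(my) == 0L) { genome[ct] <- bg[[ct]]; next }
      ord <- order(vapply(my, `[[`, numeric(1), "pos"))
      my <- my[ord]
      pieces <- character(0)
      prev <- 0L
      shift <- 0L
      for (x in my) {
        pieces <- c(pieces, substr(bg[[ct]], prev + 1L, x$pos),
                    x$tsd, x$seq, x$tsd)
        elem_start <- x$pos + shift + nchar(x$tsd) + 1L
        truth[[length(truth) + 1L]] <- data.frame(
          contig = contig_names[ct], start = elem_start,
          end = elem_start + nchar(x$seq) - 1L, strand = x$strand,
          family_id = x$family_id, superfamily = x$superfamily,
          order = x$order, completeness = x$completeness,
          divergence = divergence, tsd = x$tsd, stringsAsFactors = FALSE)
        shift <- shift + 2L * nchar(x$tsd) + nchar(x$seq)
        prev <- x$pos
      }
      pieces <- c(pieces, substr(bg[[ct]], prev + 1L, cw[ct]))
      genome[ct] <- paste(pieces, collapse = "")
    }
    gs <- DNAStringSet(genome)
    names(gs) <- contig_names
    if (length(truth)) {
      td <- do.call(rbind, truth)
      gr <- GRanges(td$contig, IRanges(td$start, td$end), strand = td$strand,
                    family_id = td$family_id, superfamily = td$superfamily,
                    order = td$order, completeness = td$completeness,
                    divergence = td$divergence, tsd = td$tsd)
    } else {
      gr <- GRanges()
    }
    list(genome = gs, truth = gr)
  })
}

#' Simulate error-free shotgun reads from a genome
#'
#' Reads are drawn uniformly from both strands;
#' \code{count = ceiling(depth * total_bp / read_len)}.
#'
#' @param genome named DNAStringSet
#' @param read_len read length (must not exceed the shortest contig)
#' @param depth fold coverage
#' @param seed integer seed
#' @param error_rate per-base substitution rate (default 0, error-free)
#' @return named DNAStringSet of reads
#' @export
simulateReads <- function(genome, read_len = 100L, depth = 10, seed = 1L,
                          error_rate = 0) {
  if (read_len > min(width(genome)))
    .stopf("read_len %d exceeds the shortest contig (%d bp)",
           read_len, min(width(genome)))
  total_bp <- sum(width(genome))
  n <- ceiling(depth * total_bp / read_len)
  withSeed(as.integer(seed) + 13L, {
    gc_ <- as.character(genome)
    ct <- sample.int(length(genome), n, replace = TRUE, prob = width(genome))
    pos <- floor(runif(n) * (width(genome)[ct] - read_len + 1L)) + 1L
    st <- sample(c("+", "-"), n, replace = TRUE)
    reads <- substr(gc_[ct], pos, pos + read_len - 1L)
    if (error_rate > 0) {
      for (i in seq_len(n)) {
        hit <- which(runif(read_len) < error_rate)
        if (length(hit)) {
          ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
          for (p in hit) ch[p] <- sample(setdiff(c("A","C","G","T"), ch[p]), 1)
          reads[i] <- paste(ch, collapse = "")
        }
      }
    }
    out <- DNAStringSet(reads)
    minus <- st == "-"
    if (any(minus)) out[minus] <- reverseComplement(out[minus])
    names(out) <- paste0("read_", seq_len(n))
    out
  })
}

#' Simulate transcript coverage and tryptic-like peptides
#'
#' Copies of expressed families receive a transcript interval covering at
#' least 95\% of their span; all other copies receive at most 50\%.
#' Peptides are 8--25-residue substrings of the family-specific segment of
#' the transposase ORF of the peptide-source families.
#'
#' @param truth PlantedTruth GRanges from \code{\link{plantCopies}}
#' @param expressed_families character vector of family ids
#' @param peptide_source_families character vector of family ids (must carry
#'   a transposase ORF)
#' @param templates list of TETemplate used when planting
#' @param seed the seed used when planting (peptides are recomputed from it)
#' @param n_peptides peptides per source family
#' @param tx_flank expressed transcript intervals extend this many bp past
#'   the element boundaries (transcriptional read-through), so annotated
#'   copies that carry modest detector flanks still show full coverage
#' @return list(transcripts = GRanges, coverage = data.frame(copy_id,
#'   covered_fraction), peptides = AAStringSet)
#' @export
simulateActivity <- function(truth, expressed_families, peptide_source_families,
                             templates, seed = 1L, n_peptides = 6L,
                             tx_flank = 2500L) {
  fam <- mcols(truth)$family_id
  known <- unique(fam)
  bad <- setdiff(c(expressed_families, peptide_source_families), known)
  if (length(bad)) .stopf("family '%s' not present in truth", bad[1])
  ts <- templateSequences(templates, seed)
  withSeed(as.integer(seed) + 29L, {
    n <- length(truth)
    covfrac <- numeric(n)
    tx <- list()
    for (i in seq_len(n)) {
      w <- width(truth)[i]
      if (fam[i] %in% expressed_families) {
        s <- max(1L, start(truth)[i] - tx_flank)
        e <- end(truth)[i] + tx_flank
      } else {
        f <- runif(1, 0.3, 0.5)
        s <- start(truth)[i]; e <- s + max(1L, floor(w * f)) - 1L
      }
      covfrac[i] <- (min(e, end(truth)[i]) - max(s, start(truth)[i]) + 1) / w
      tx[[i]] <- data.frame(contig = as.character(seqnames(truth))[i],
                            start = s, end = e)
    }
    txd <- do.call(rbind, tx)
    transcripts <- GRanges(txd$contig, IRanges(txd$start, txd$end), strand = "*")
    copy_id <- sprintf("%s_copy%03d", fam, ave(seq_len(n), fam, FUN = seq_along))
    mcols(transcripts)$copy_id <- copy_id
    peps <- character(0)
    pnames <- character(0)
    for (f in peptide_source_families) {
      va <- ts[[f]]$var_aa
      if (nchar(va) == 0L)
        .stopf("family '%s' has no transposase ORF to draw peptides from", f)
      for (j in seq_len(n_peptides)) {
        len <- sample(8:25, 1)
        off <- sample.int(nchar(va) - len + 1L, 1)
        peps <- c(peps, substr(va, off, off + len - 1L))
        pnames <- c(pnames, sprintf("pep_%s_%d", f, j))
      }
    }
    pset <- AAStringSet(peps)
    names(pset) <- pnames
    list(transcripts = transcripts,
         coverage = data.frame(copy_id = copy_id, covered_fraction = covfrac,
                               family_id = fam, stringsAsFactors = FALSE),
         peptides = pset)
  })
}
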