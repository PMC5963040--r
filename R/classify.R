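# Evidence extraction and the rule engine assigning Wicker class, order,
# superfamily and autonomy. The engine replaces opaque classifier scoring
# with an explicit priority cascade encoding the autonomy definitions:
# autonomous LTR needs RT + INT domains plus similarity to a known LTR
# element; autonomous LINE needs RT plus LINE similarity; autonomous TIR
# needs a transposase domain (or TIR similarity with a coding ORF).

#' Extract classification evidence for one sequence
#'
#' Scans sequence termini for direct/inverted repeats (arms of at least
#' \code{terminal_arm_min} bp at \code{terminal_identity} or better),
#' records ORFs of at least \code{orf_min_len} bp in all six frames, aligns
#' the domain consensus peptides against translated ORFs, and collects
#' nucleotide similarity hits against a classified reference library with
#' mutual coverages.
#'
#' @param seq DNAString (or character) of length >= 50
#' @param nt_library a classified \linkS4class{TELibrary} (the databank)
#' @param domain_peptides named peptide vector (see
#'   \code{\link{domainPeptides}})
#' @param config a \linkS4class{TEConfig}
#' @param features optional one-row structural feature data.frame from the
#'   detector (columns repeat_kind, tsd, polyA_len)
#' @return an evidence list with elements length, terminal, orfs,
#'   domain_hits, similarity_hits, polyA_len, tsd
#' @export
extractEvidence <- function(seq, nt_library, domain_peptides = domainPeptides(),
                            config = teConfig(), features = NULL) {
  s <- as.character(seq)
  L <- nchar(s)
  if (L < 50L) .stopf("sequence too short for evidence extraction (%d bp)", L)
  arm_min <- config[["terminal_arm_min"]]
  arm_id <- config[["terminal_identity"]]
  ## terminal repeat scan: compare a head window against a tail window
  ## (capped slightly above the largest expected LTR arm)
  w <- max(50L, min(L %/% 3L, 1100L))
  headseq <- substr(s, 1L, w)
  tailseq <- substr(s, L - w + 1L, L)
  terminal <- list(repeat_kind = "none", repeat_len = 0L, repeat_identity = 0)
  near_edge <- 30L
  dstat <- alignPair(headseq, tailseq)
  darm <- min(dstat$q_end - dstat$q_start, dstat$s_end - dstat$s_start) + 1L
  if (darm >= arm_min && dstat$identity >= arm_id &&
      dstat$q_start <= near_edge && dstat$s_end >= w - near_edge)
    terminal <- list(repeat_kind = "direct_pair", repeat_len = darm,
                     repeat_identity = dstat$identity)
  istat <- alignPair(headseq, rcChar(tailseq))
  iarm <- min(istat$q_end - istat$q_start, istat$s_end - istat$s_start) + 1L
  if (terminal$repeat_kind == "none" &&
      iarm >= arm_min && istat$identity >= arm_id &&
      istat$q_start <= near_edge && istat$s_start <= near_edge)
    terminal <- list(repeat_kind = "inverted_pair", repeat_len = iarm,
                     repeat_identity = istat$identity)
  ## ORFs and domain hits
  orfs <- findORFs(s, config[["orf_min_len"]])
  domain_hits <- list()
  if (nrow(orfs) > 0L) {
    for (i in seq_len(nrow(orfs))) {
      for (tok in names(domain_peptides)) {
        pa <- .peptideAlign(domain_peptides[[tok]], orfs$aa[i])
        if (score(pa) >= config[["domain_min_score"]])
          domain_hits[[length(domain_hits) + 1L]] <- data.frame(
            token = tok, score = score(pa), frame = orfs$frame[i],
            start = orfs$start[i], end = orfs$end[i], stringsAsFactors = FALSE)
      }
    }
  }
  domain_hits <- if (length(domain_hits)) do.call(rbind, domain_hits)
    else data.frame(token = character(0), score = numeric(0),
                    frame = integer(0), start = integer(0), end = integer(0))
  ## nucleotide similarity vs the classified library
  sim <- list()
  lib_seqs <- librarySeqs(nt_library)
  lib_cls <- libraryClassification(nt_library)
  for (j in seq_along(lib_seqs)) {
    subj <- as.character(lib_seqs[[j]])
    if (sharedKmerFrac(substr(s, 1, min(L, 20000L)), subj, k = 12L) == 0) next
    hits <- pairHits(s, subj, min_identity = config[["min_identity"]],
                     min_len = config[["family_min_len"]])
    if (nrow(hits) == 0L) next
    scov_union <- sum(width(reduce(IRanges(hits$s_start, hits$s_end)))) / nchar(subj)
    qcov_union <- sum(width(reduce(IRanges(hits$q_start, hits$q_end)))) / L
    best <- hits[which.max(hits$score), ]
    sim[[length(sim) + 1L]] <- data.frame(
      subject_id = names(lib_seqs)[j],
      subject_class = lib_cls$wicker_class[j], subject_order = lib_cls$order[j],
      subject_superfamily = lib_cls$superfamily[j],
      pct_identity = best$identity, query_cov = qcov_union,
      subject_cov = scov_union, score = best$score, stringsAsFactors = FALSE)
  }
  sim <- if (length(sim)) do.call(rbind, sim)
    else data.frame(subject_id = character(0), subject_class = character(0),
                    subject_order = character(0),
                    subject_superfamily = character(0),
                    pct_identity = numeric(0), query_cov = numeric(0),
                    subject_cov = numeric(0), score = numeric(0))
  pa_len <- polyATail(s, min_run = 8L)
  tsd <- if (!is.null(features) && !is.na(features$tsd)) features$tsd else NA_character_
  if (!is.null(features) && !is.na(features$repeat_kind) &&
      features$repeat_kind != "none" && terminal$repeat_kind == "none")
    terminal$repeat_kind <- features$repeat_kind
  list(length = L, terminal = terminal, orfs = orfs, domain_hits = domain_hits,
       similarity_hits = sim, polyA_len = pa_len, tsd = tsd)
}

# Superfamily call: score-weighted majority over similarity hits (optionally
# restricted to the assigned order). Plain subject counting would mis-assign
# when conserved domain regions cross superfamilies.
.majoritySuperfamily <- function(sim, ord = NULL) {
  if (nrow(sim) == 0L) return("unknown")
  if (!is.null(ord)) sim <- sim[sim$subject_order == ord, , drop = FALSE]
  sim <- sim[!sim$subject_superfamily %in% c("none", "unknown"), , drop = FALSE]
  if (nrow(sim) == 0L) return("unknown")
  w <- tapply(sim$score, sim$subject_superfamily, sum)
  names(w)[order(-w, names(w))[1]]
}

.classOf <- function(order) {
  switch(order,
         LTR = , LINE = , SINE = , TRIM = , LARD = "I",
         TIR = , MITE = , Helitron = "II",
         "unknown")
}

#' Classify one evidence bundle under the Wicker rule cascade
#'
#' Rules fire in priority order; the first match wins. See the package
#' vignette for the full cascade and its reading of the autonomy
#' definitions.
#'
#' @param ev evidence list from \code{\link{extractEvidence}}
#' @param config a \linkS4class{TEConfig}
#' @return list(wicker_class, order, superfamily, autonomy, evidence_used)
#' @export
classifySequence <- function(ev, config = teConfig()) {
  toks <- unique(ev$domain_hits$token)
  sim <- ev$similarity_hits
  has_order_sim <- function(ord) any(sim$subject_order == ord)
  res <- function(order, superfamily, autonomy, rules) {
    list(wicker_class = .classOf(order), order = order,
         superfamily = superfamily, autonomy = autonomy,
         evidence_used = rules)
  }
  ## (1) autonomous LTR: RT and INT domains plus LTR similarity
  if (all(c("RT", "INT") %in% toks) && has_order_sim("LTR"))
    return(res("LTR", .majoritySuperfamily(sim, "LTR"), "autonomous",
               "RT+INT+LTR_similarity"))
  ## (2) autonomous LINE: RT domain plus LINE similarity
  if ("RT" %in% toks && has_order_sim("LINE"))
    return(res("LINE", .majoritySuperfamily(sim, "LINE"), "autonomous",
               "RT+LINE_similarity"))
  ## (3) autonomous TIR: transposase domain, or TIR similarity with a
  ##     coding ORF present
  if ("TASE" %in% toks)
    return(res("TIR", .majoritySuperfamily(sim, "TIR"), "autonomous",
               "TASE_domain"))
  if (has_order_sim("TIR") && nrow(ev$orfs) > 0L)
    return(res("TIR", .majoritySuperfamily(sim, "TIR"), "autonomous",
               "TIR_similarity+ORF"))
  ## (4) LTR-derived non-coding: direct terminal pair without domains
  if (ev$terminal$repeat_kind == "direct_pair" && length(toks) == 0L) {
    ord <- if (ev$length <= config[["trim_lard_boundary"]]) "TRIM" else "LARD"
    return(res(ord, "none", "non_autonomous", "direct_pair_no_domains"))
  }
  ## (5) MITE: inverted terminal pair, no ORF, short
  if (ev$terminal$repeat_kind == "inverted_pair" && nrow(ev$orfs) == 0L &&
      ev$length <= config[["mite_max_len"]])
    return(res("MITE", "none", "non_autonomous", "inverted_pair_no_orf"))
  ## (6) SINE: poly-A tail, TSD evidence, SINE-range length, no domains
  sr <- config[["sine_len_range"]]
  if (ev$polyA_len >= config[["sine_min_tail"]] && !is.na(ev$tsd) &&
      ev$length >= sr[1] && ev$length <= sr[2] && length(toks) == 0L)
    return(res("SINE", "none", "non_autonomous", "polyA+TSD"))
  ## (7) similarity inheritance
  good <- sim[sim$pct_identity >= 0.8 & sim$subject_cov >= 0.5, , drop = FALSE]
  if (nrow(good) > 0L) {
    best <- good[order(-good$score, good$subject_id), , drop = FALSE][1, ]
    ord <- best$subject_order
    sf <- .majoritySuperfamily(good, ord)
    supporting <- switch(ord, LTR = , LINE = c("RT"), TIR = "TASE", character(0))
    aut <- if (ord %in% c("LTR", "LINE", "TIR", "Helitron") &&
               length(supporting) && all(supporting %in% toks))
      "autonomous" else "non_autonomous"
    if (ord %in% c("SINE", "MITE", "TRIM", "LARD")) { aut <- "non_autonomous"; sf <- "none" }
    return(res(ord, sf, aut, "similarity_inheritance"))
  }
  ## (8) fallback
  res("noCat", "unknown", "uncategorized", "no_evidence")
}

#' Classify a candidate set
#'
#' Runs \code{\link{extractEvidence}} and \code{\link{classifySequence}} on
#' every candidate.
#'
#' @param candidates a \linkS4class{TECandidates}
#' @param nt_library classified \linkS4class{TELibrary}
#' @param domain_peptides named peptide vector
#' @param config a \linkS4class{TEConfig}
#' @return DataFrame (wicker_class, order, superfamily, autonomy, rules) with
#'   one row per candidate
#' @export
classifyCandidates <- function(candidates, nt_library,
                               domain_peptides = domainPeptides(),
                               config = teConfig()) {
  n <- length(candidates)
  out <- vector("list", n)
  info <- candidateInfo(candidates)
  seqs <- candidateSeqs(candidates)
  for (i in seq_len(n)) {
    feats <- data.frame(repeat_kind = info$repeat_kind[i], tsd = info$tsd[i],
                        polyA_len = info$polyA_len[i], stringsAsFactors = FALSE)
    ev <- extractEvidence(seqs[[i]], nt_library, domain_peptides, config, feats)
    out[[i]] <- classifySequence(ev, config)
  }
  df <- DataFrame(
    wicker_class = vapply(out, `[[`, character(1), "wicker_class"),
    order = vapply(out, `[[`, character(1), "order"),
    superfamily = vapply(out, `[[`, character(1), "superfamily"),
    autonomy = vapply(out, `[[`, character(1), "autonomy"),
    rules = vapply(out, function(x) paste(x$evidence_used, collapse = ";"),
                   character(1)))
  rownames(df) <- names(seqs)
  df
}

#' Partition classified candidates by autonomy
#'
#' @param classification DataFrame from \code{\link{classifyCandidates}}
#' @return list of row-index vectors: autonomous, non_autonomous, noCat
#' @export
partitionByAutonomy <- function(classification) {
  aut <- classification$autonomy
  list(autonomous = which(aut == "autonomous"),
       non_autonomous = which(aut == "non_autonomous"),
       noCat = which(aut == "uncategorized"))
}
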