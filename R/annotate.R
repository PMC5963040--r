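# Two-pass Russian-doll genome annotation: align each nested library to the
# genome, keep full-length-copy (FLC) entries, re-annotate with the FLC
# library, resolve overlaps, and account genome proportions per category.

#' Align a library against the genome
#'
#' All local alignments of each library entry against both strands at
#' \code{min_identity} or better and at least \code{min_len} bp. Co-linear
#' fragments of the same entry on the same strand separated by at most
#' \code{chain_gap} bp are chained into one interval, summing library
#' coverage.
#'
#' @param lib a \linkS4class{TELibrary}
#' @param genome named DNAStringSet
#' @param min_identity,min_len,chain_gap see description
#' @param cache optional environment memoizing per-entry hits across the
#'   two passes and the three nested libraries (the aligner is
#'   deterministic, so cached results are identical to recomputation)
#' @return GRanges with mcols library_id, pct_identity, library_coverage,
#'   score, plus the entry classification columns
#' @export
alignLibraryToGenome <- function(lib, genome, min_identity = 0.8,
                                 min_len = 80L, chain_gap = 500L,
                                 cache = NULL) {
  seqs <- librarySeqs(lib)
  cls <- libraryClassification(lib)
  all_rows <- list()
  for (li in seq_along(seqs)) {
    id <- names(seqs)[li]
    key <- paste0("hits::", id)
    hits_all <- NULL
    if (!is.null(cache) && exists(key, envir = cache, inherits = FALSE)) {
      hits_all <- get(key, envir = cache)
    } else {
      q <- as.character(seqs[[li]])
      per_contig <- list()
      for (ci in seq_along(genome)) {
        h <- seedExtendHits(q, genome[[ci]], min_identity = min_identity,
                            min_len = min_len)
        if (nrow(h) > 0L) {
          h$contig <- names(genome)[ci]
          per_contig[[length(per_contig) + 1L]] <- h
        }
      }
      hits_all <- if (length(per_contig)) do.call(rbind, per_contig)
        else data.frame()
      if (!is.null(cache)) assign(key, hits_all, envir = cache)
    }
    if (nrow(hits_all) == 0L) next
    ch <- .chainHits(hits_all, qlen = width(seqs)[li], chain_gap = chain_gap)
    ch$library_id <- id
    ch$order <- cls$order[li]
    ch$superfamily <- cls$superfamily[li]
    ch$wicker_class <- cls$wicker_class[li]
    ch$autonomy <- cls$autonomy[li]
    all_rows[[length(all_rows) + 1L]] <- ch
  }
  if (length(all_rows) == 0L)
    return(GRanges(library_id = character(0), pct_identity = numeric(0),
                   library_coverage = numeric(0), score = numeric(0)))
  rd <- do.call(rbind, all_rows)
  gr <- GRanges(rd$contig, IRanges(rd$s_start, rd$s_end), strand = rd$strand,
                library_id = rd$library_id, pct_identity = rd$identity,
                library_coverage = pmin(rd$qcov, 1), score = rd$score,
                order = rd$order, superfamily = rd$superfamily,
                wicker_class = rd$wicker_class, autonomy = rd$autonomy)
  sort(gr, ignore.strand = TRUE)
}

# Chain co-linear same-strand hits of one library entry per contig.
.chainHits <- function(hits, qlen, chain_gap = 500L) {
  out <- list()
  for (ct in unique(hits$contig)) {
    for (st in unique(hits$strand[hits$contig == ct])) {
      h <- hits[hits$contig == ct & hits$strand == st, , drop = FALSE]
      h <- h[order(h$s_start), , drop = FALSE]
      grp <- cumsum(c(TRUE, h$s_start[-1] - h$s_end[-nrow(h)] > chain_gap))
      for (g in unique(grp)) {
        hh <- h[grp == g, , drop = FALSE]
        qcov <- sum(width(reduce(IRanges(hh$q_start, hh$q_end)))) / qlen
        alen <- hh$s_end - hh$s_start + 1L
        out[[length(out) + 1L]] <- data.frame(
          contig = ct, s_start = min(hh$s_start), s_end = max(hh$s_end),
          strand = st, identity = sum(hh$identity * alen) / sum(alen),
          qcov = qcov, score = sum(hh$score), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Select full-length-copy (FLC) library entries
#'
#' An entry is retained iff at least one of its (chained) intervals covers
#' \code{flc_cov} of the entry length — purging fragments and potential
#' chimeras before the second annotation pass.
#'
#' @param intervals GRanges from \code{\link{alignLibraryToGenome}}
#' @param lib the library those intervals came from
#' @param flc_cov minimum library coverage
#' @return the FLC subset of \code{lib}
#' @export
selectFLC <- function(intervals, lib, flc_cov = 0.95) {
  if (length(intervals) == 0L) return(lib[integer(0)])
  best <- tapply(mcols(intervals)$library_coverage,
                 mcols(intervals)$library_id, max)
  keep_ids <- names(best)[best >= flc_cov]
  lib[names(librarySeqs(lib)) %in% keep_ids]
}

# Greedy overlap resolution: higher score wins; losers are trimmed to their
# non-overlapping remainder and kept only if >= min_len bp survives.
.resolveOverlaps <- function(gr, min_len = 80L) {
  if (length(gr) <= 1L) return(gr)
  md <- mcols(gr)
  o <- order(-md$score, -width(gr), md$library_id,
             as.integer(factor(as.character(seqnames(gr)))), start(gr))
  gr <- gr[o]
  occupied <- list()
  out <- list()
  for (i in seq_along(gr)) {
    ct <- as.character(seqnames(gr))[i]
    r <- IRanges(start(gr)[i], end(gr)[i])
    occ <- occupied[[ct]]
    rem <- if (is.null(occ)) r else IRanges::setdiff(r, occ)
    rem <- rem[width(rem) >= min_len]
    if (length(rem) > 0L) {
      for (j in seq_along(rem)) {
        piece <- gr[i]
        start(piece) <- start(rem)[j]
        end(piece) <- end(rem)[j]
        out[[length(out) + 1L]] <- piece
      }
      occupied[[ct]] <- if (is.null(occ)) reduce(rem) else reduce(c(occ, rem))
    }
  }
  res <- do.call(c, out)
  sort(res, ignore.strand = TRUE)
}

#' Second-pass annotation with an FLC library
#'
#' Re-aligns the FLC library and resolves overlapping intervals: the higher
#' score wins; the loser is trimmed to its non-overlapping remainder and
#' kept only if at least \code{min_len} bp remains. Ties break by longer
#' interval, then smaller library id.
#'
#' @param flc_lib FLC library from \code{\link{selectFLC}}
#' @param genome named DNAStringSet
#' @param min_identity,min_len,chain_gap alignment parameters
#' @param cache optional memoization environment
#' @return GRanges of non-overlapping annotation intervals
#' @export
annotateGenome <- function(flc_lib, genome, min_identity = 0.8,
                           min_len = 80L, chain_gap = 500L, cache = NULL) {
  gr <- alignLibraryToGenome(flc_lib, genome, min_identity = min_identity,
                             min_len = min_len, chain_gap = chain_gap,
                             cache = cache)
  .resolveOverlaps(gr, min_len = min_len)
}

#' Genome proportions per category
#'
#' For each level of the grouping column, the percentage of genome bp
#' covered by the union of that category's intervals (overlaps within a
#' category counted once), rounded half-up to 2 decimals.
#'
#' @param intervals annotation GRanges
#' @param genome named DNAStringSet
#' @param grouping mcols column name ("order", "superfamily",
#'   "wicker_class", "library_id") or NULL for the overall proportion
#' @return data.frame(category, bp, pct); for NULL grouping a single row
#'   "all"
#' @export
computeProportions <- function(intervals, genome, grouping = NULL) {
  genome_bp <- sum(width(genome))
  if (length(intervals) > 0L) .checkBounds(intervals, genome)
  cats <- if (is.null(grouping)) rep("all", length(intervals))
    else as.character(mcols(intervals)[[grouping]])
  levs <- sort(unique(cats))
  if (length(intervals) == 0L)
    return(data.frame(category = if (is.null(grouping)) "all" else character(0),
                      bp = if (is.null(grouping)) 0L else integer(0),
                      pct = if (is.null(grouping)) 0 else numeric(0),
                      stringsAsFactors = FALSE))
  res <- lapply(levs, function(cv) {
    u <- reduce(granges(intervals[cats == cv]), ignore.strand = TRUE)
    bp <- sum(width(u))
    data.frame(category = cv, bp = bp,
               pct = roundHalfUp(100 * bp / genome_bp, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Run the full two-pass Russian-doll annotation
#'
#' Each nested library is annotated independently (first pass, FLC
#' selection, second pass) to avoid competition among library sequences
#' aligning to the same genomic regions. The report carries the three
#' per-run proportions and the derived quantities: non-autonomous \% =
#' total TE \% - autonomous \%; uncategorized-repeat \% = repeated \% -
#' total TE \%.
#'
#' @param libs list(autonomous, total, repeated) of nested
#'   \linkS4class{TELibrary}
#' @param genome named DNAStringSet
#' @param config a \linkS4class{TEConfig}
#' @param cache optional memoization environment shared across runs
#' @return list(annotations, flc_libs, report)
#' @export
runRussianDoll <- function(libs, genome, config = teConfig(), cache = NULL) {
  ids <- lapply(libs, function(l) names(librarySeqs(l)))
  if (!(all(ids$autonomous %in% ids$total) && all(ids$total %in% ids$repeated)))
    .stopf("nesting violation: autonomous must be within total within repeated")
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  ann <- list(); flc <- list()
  for (nm in c("autonomous", "total", "repeated")) {
    first <- alignLibraryToGenome(libs[[nm]], genome,
                                  min_identity = config[["min_identity"]],
                                  min_len = config[["anno_min_len"]],
                                  chain_gap = config[["chain_gap"]],
                                  cache = cache)
    fl <- selectFLC(first, libs[[nm]], flc_cov = config[["flc_cov"]])
    flc[[nm]] <- fl
    ann[[nm]] <- annotateGenome(fl, genome,
                                min_identity = config[["min_identity"]],
                                min_len = config[["anno_min_len"]],
                                chain_gap = config[["chain_gap"]],
                                cache = cache)
  }
  pct_of <- function(gr) {
    p <- computeProportions(gr, genome, grouping = NULL)
    if (nrow(p) == 0L) 0 else p$pct[1]
  }
  report <- list(
    autonomous_pct = pct_of(ann$autonomous),
    total_te_pct = pct_of(ann$total),
    repeated_pct = pct_of(ann$repeated),
    by_order = computeProportions(ann$total, genome, "order"),
    by_superfamily = computeProportions(ann$total, genome, "superfamily"),
    by_class = computeProportions(ann$total, genome, "wicker_class"))
  report$non_autonomous_pct <- roundHalfUp(report$total_te_pct -
                                             report$autonomous_pct, 2)
  report$uncategorized_repeat_pct <- roundHalfUp(report$repeated_pct -
                                                   report$total_te_pct, 2)
  list(annotations = ann, flc_libs = flc, report = report)
}

#' Export an annotation as BED plus a per-contig summary TSV
#'
#' BED name fields carry \code{superfamily|library_id}; the TSV counts
#' copies per contig per superfamily.
#'
#' @param intervals annotation GRanges
#' @param genome named DNAStringSet
#' @param bed_path,tsv_path output paths
#' @return invisible list of the two paths
#' @export
exportCartography <- function(intervals, genome, bed_path, tsv_path) {
  if (length(intervals) > 0L) .checkBounds(intervals, genome)
  nm <- if (length(intervals) > 0L)
    paste(mcols(intervals)$superfamily, mcols(intervals)$library_id, sep = "|")
  else character(0)
  gr <- granges(intervals)
  if (length(gr) > 0L) mcols(gr)$name <- nm
  rtracklayer::export(gr, bed_path, format = "BED")
  if (length(intervals) > 0L) {
    df <- data.frame(contig = as.character(seqnames(intervals)),
                     superfamily = mcols(intervals)$superfamily,
                     stringsAsFactors = FALSE)
    agg <- as.data.frame(table(df$contig, df$superfamily),
                         stringsAsFactors = FALSE)
    colnames(agg) <- c("contig", "superfamily", "n_copies")
    agg <- agg[agg$n_copies > 0, , drop = FALSE]
    agg <- agg[order(agg$contig, agg$superfamily), , drop = FALSE]
  } else {
    agg <- data.frame(contig = character(0), superfamily = character(0),
                      n_copies = integer(0))
  }
  write.table(agg, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(bed = bed_path, tsv = tsv_path))
}
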