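# Coverage-score benchmarking of a detected set against a reference family
# library, order-level classification assessment, and per-approach
# contribution ratios.

#' Coverage score of a detected sequence against a reference consensus
#'
#' The fraction of the reference length covered by the union of local
#' alignments (at \code{min_identity} or better, either strand) between the
#' detected sequence and the reference. Computed on the reference length:
#' below 0.40 a family counts as undetected, 0.40--0.70 as partial, at or
#' above 0.70 as complete.
#'
#' @param detected,reference sequences (character or DNAString)
#' @param min_identity minimum alignment identity
#' @param min_len minimum alignment length (bp)
#' @return fraction in [0, 1]
#' @export
coverageScore <- function(detected, reference, min_identity = 0.8,
                          min_len = 80L) {
  d <- as.character(detected); r <- as.character(reference)
  if (nchar(d) == 0L || nchar(r) == 0L) .stopf("empty sequence")
  if (sharedKmerFrac(d, r, k = 12L) == 0) return(0)
  hits <- pairHits(d, r, min_identity = min_identity, min_len = min_len)
  if (nrow(hits) == 0L) return(0)
  sum(width(reduce(IRanges(hits$s_start, hits$s_end)))) / nchar(r)
}

#' Benchmark a detected set against a reference library
#'
#' Per reference family, the best coverage over all detected sequences,
#' with status assigned at the partial/complete thresholds and the approach
#' of the argmax recorded (ties: longer detected sequence, then smaller id).
#'
#' @param detected a \linkS4class{TECandidates}
#' @param reference a \linkS4class{TELibrary} of reference family consensi
#' @param partial_cov,complete_cov status thresholds
#' @param exclude reference ids to leave out of the benchmark
#' @return data.frame(ref_id, order, best_coverage, status,
#'   best_detected_id, best_approach)
#' @export
benchmarkDetection <- function(detected, reference, partial_cov = 0.40,
                               complete_cov = 0.70, exclude = character(0)) {
  refs <- librarySeqs(reference)
  refs <- refs[!names(refs) %in% exclude]
  rcls <- libraryClassification(reference)[!names(librarySeqs(reference)) %in% exclude, ,
                                           drop = FALSE]
  dseqs <- candidateSeqs(detected)
  dinfo <- candidateInfo(detected)
  out <- list()
  for (ri in seq_along(refs)) {
    best_cov <- 0; best_id <- NA_character_; best_app <- NA_character_
    best_w <- -1L
    for (di in seq_along(dseqs)) {
      cov <- coverageScore(dseqs[[di]], refs[[ri]])
      w <- width(dseqs)[di]
      id <- names(dseqs)[di]
      better <- cov > best_cov ||
        (cov == best_cov && cov > 0 &&
           (w > best_w || (w == best_w && (is.na(best_id) || id < best_id))))
      if (better) {
        best_cov <- cov; best_id <- id; best_w <- w
        best_app <- dinfo$approach[di]
      }
    }
    status <- if (best_cov >= complete_cov) "complete"
      else if (best_cov >= partial_cov) "partial" else "undetected"
    out[[ri]] <- data.frame(ref_id = names(refs)[ri], order = rcls$order[ri],
                            best_coverage = best_cov, status = status,
                            best_detected_id = best_id,
                            best_approach = best_app, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Summarize a detection benchmark
#'
#' Per order and overall: the percentage of reference families detected at
#' the partial (>= 0.40) and complete (>= 0.70) coverage thresholds.
#' Display percentages are integers, rounded half-up.
#'
#' @param records data.frame from \code{\link{benchmarkDetection}} (or any
#'   data.frame with columns order and best_coverage / counts)
#' @param partial_cov,complete_cov thresholds
#' @return list(per_order = data.frame, overall = list(n_detected, n_total,
#'   pct))
#' @export
summarizeDetection <- function(records, partial_cov = 0.40,
                               complete_cov = 0.70) {
  det40 <- records$best_coverage >= partial_cov
  det70 <- records$best_coverage >= complete_cov
  per_order <- do.call(rbind, lapply(sort(unique(records$order)), function(o) {
    i <- records$order == o
    data.frame(order = o, n_families = sum(i),
               pct_detected_at_40 = roundHalfUp(100 * sum(det40 & i) / sum(i)),
               pct_detected_at_70 = roundHalfUp(100 * sum(det70 & i) / sum(i)),
               stringsAsFactors = FALSE)
  }))
  list(per_order = per_order,
       overall = list(n_detected = sum(det40), n_total = nrow(records),
                      pct = roundHalfUp(100 * sum(det40) / nrow(records))))
}

#' Assess classification correctness at the order level
#'
#' Correct iff the predicted order equals the true order (MITE, TRIM and
#' LARD count as their own orders); noCat predictions are uncategorized;
#' anything else is incorrect. Percentages are integer, half-up.
#'
#' @param predicted named character vector (or DataFrame with an order
#'   column) of predicted orders, names are sequence ids
#' @param truth named character vector of true orders over the same ids
#' @return list(n_correct, n_incorrect, n_uncategorized, pct_correct,
#'   pct_incorrect, pct_uncategorized, n)
#' @export
assessClassification <- function(predicted, truth) {
  if (is(predicted, "DataFrame") || is.data.frame(predicted)) {
    p <- setNames(as.character(predicted$order), rownames(predicted))
  } else p <- predicted
  if (!setequal(names(p), names(truth)))
    .stopf("predicted and truth id sets differ")
  p <- p[names(truth)]
  unc <- p == "noCat"
  correct <- !unc & p == truth
  incorrect <- !unc & !correct
  n <- length(p)
  list(n_correct = sum(correct), n_incorrect = sum(incorrect),
       n_uncategorized = sum(unc),
       pct_correct = roundHalfUp(100 * sum(correct) / n),
       pct_incorrect = roundHalfUp(100 * sum(incorrect) / n),
       pct_uncategorized = roundHalfUp(100 * sum(unc) / n),
       n = n)
}

#' Per-approach contribution ratios
#'
#' Over detected families only (status not "undetected"): the fraction of
#' families whose best-covering detection came from each approach. Ratios
#' sum to 1 whenever at least one family is detected.
#'
#' @param records data.frame from \code{\link{benchmarkDetection}}
#' @return named numeric vector of ratios (empty if nothing detected)
#' @export
approachContribution <- function(records) {
  det <- records[records$status != "undetected", , drop = FALSE]
  if (nrow(det) == 0L) return(setNames(numeric(0), character(0)))
  tb <- table(det$best_approach)
  setNames(as.numeric(tb) / nrow(det), names(tb))
}
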