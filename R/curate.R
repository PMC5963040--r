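# Step-1 post-processing: length filtering of the similarity and read-based
# approaches, exact-containment redundancy reduction, and routing of
# MITE/SINE structural detections straight to the non-autonomous bin.

#' Length-filter detections from the similarity and read-based approaches
#'
#' Sequences below \code{min_len} bp are removed; sequences exactly at the
#' boundary are retained. Structural and repetitiveness detections are not
#' subject to the filter and pass through untouched.
#'
#' @param candidates a \linkS4class{TECandidates}
#' @param min_len minimum retained length (bp)
#' @return filtered TECandidates
#' @export
filterMinLength <- function(candidates, min_len = 500L) {
  stopifnot(min_len > 0L)
  if (length(candidates) == 0L) return(candidates)
  subject_to <- candidateInfo(candidates)$approach %in% c("similarity", "read_based")
  keep <- !subject_to | width(candidateSeqs(candidates)) >= min_len
  candidates[keep]
}

#' Redundancy reduction by exact containment
#'
#' A sequence is removed iff it is an exact substring (100\% identity over
#' 100\% of its own length) of a longer kept sequence, in forward or
#' reverse-complement orientation. Processing is greedy longest-first; among
#' equal-length duplicates the lexicographically smallest id is kept.
#' Near-exact containment is never removed here (family clustering handles
#' near-duplicates later).
#'
#' @param candidates a \linkS4class{TECandidates}
#' @return list(kept = TECandidates, removed = data.frame(removed_id,
#'   container_id, orientation))
#' @export
reduceRedundancy <- function(candidates) {
  n <- length(candidates)
  removed <- data.frame(removed_id = character(0), container_id = character(0),
                        orientation = character(0), stringsAsFactors = FALSE)
  if (n <= 1L) return(list(kept = candidates, removed = removed))
  seqs <- candidateSeqs(candidates)
  ids <- names(seqs)
  o <- order(-width(seqs), ids)
  kept_idx <- integer(0)
  rem <- list()
  for (i in o) {
    s <- seqs[[i]]
    container <- NA_character_
    orientation <- NA_character_
    if (length(kept_idx) > 0L) {
      pool <- seqs[kept_idx]
      fwd <- vcountPattern(s, pool) > 0L
      if (any(fwd)) {
        container <- ids[kept_idx[which(fwd)[1]]]
        orientation <- "forward"
      } else {
        rcv <- vcountPattern(reverseComplement(s), pool) > 0L
        if (any(rcv)) {
          container <- ids[kept_idx[which(rcv)[1]]]
          orientation <- "reverse_complement"
        }
      }
    }
    if (is.na(container)) {
      kept_idx <- c(kept_idx, i)
    } else {
      rem[[length(rem) + 1L]] <- data.frame(
        removed_id = ids[i], container_id = container,
        orientation = orientation, stringsAsFactors = FALSE)
    }
  }
  kept_idx <- sort(kept_idx)
  if (length(rem)) removed <- do.call(rbind, rem)
  list(kept = candidates[kept_idx], removed = removed)
}

#' Route detections to classification or directly to the non-autonomous bin
#'
#' Output of the TIR/MITE and SINE structural detectors bypasses
#' classification and carries preset classifications (MITE, SINE); all other
#' detections proceed to the classifier.
#'
#' @param candidates a \linkS4class{TECandidates}
#' @return list(to_classify = TECandidates, direct_nonautonomous =
#'   TECandidates, direct_classification = DataFrame)
#' @export
routeDetections <- function(candidates) {
  info <- candidateInfo(candidates)
  direct <- info$detector %in% c("tir_mite", "sine_finder")
  dc <- candidates[direct]
  di <- candidateInfo(dc)
  cls <- DataFrame(
    wicker_class = ifelse(di$detector == "tir_mite", "II", "I"),
    order = ifelse(di$detector == "tir_mite", "MITE", "SINE"),
    superfamily = rep("none", length(dc)),
    autonomy = rep("non_autonomous", length(dc)))
  rownames(cls) <- names(candidateSeqs(dc))
  list(to_classify = candidates[!direct],
       direct_nonautonomous = dc,
       direct_classification = cls)
}
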