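# Genome-proportion report arithmetic. The annotation of a genome with the
# three nested libraries yields per-run proportions; the published-style
# summary combines them with the simple-repeat and coding-gene proportions.

#' Class and order totals from per-category genome proportions
#'
#' Sums per-superfamily (or per-order) proportions within each Wicker class
#' and overall, as printed in TE inventory tables.
#'
#' @param proportions data.frame with columns \code{wicker_class} and
#'   \code{pct} (one row per superfamily/order category)
#' @return list(class_pct = named vector, total_te_pct)
#' @export
classTotals <- function(proportions) {
  stopifnot(all(c("wicker_class", "pct") %in% colnames(proportions)))
  cls <- tapply(proportions$pct, proportions$wicker_class, sum)
  cls <- roundHalfUp(as.numeric(cls), 2) |> setNames(names(cls))
  list(class_pct = cls, total_te_pct = roundHalfUp(sum(proportions$pct), 2))
}

#' Combined repeat-content summary of a genome
#'
#' Given the proportions from the nested annotation runs plus the
#' simple-tandem-repeat proportion (computed externally) and, optionally,
#' the coding-gene proportion:
#' total repeats = total TE + uncategorized repeats + simple repeats;
#' non-characterized = 100 - total repeats - coding;
#' non-autonomous TE = total TE - autonomous TE.
#'
#' @param total_te_pct proportion of the genome annotated with the total TE
#'   library (\%)
#' @param uncategorized_repeat_pct proportion from the repeated-elements run
#'   in excess of the total TE run (\%)
#' @param simple_repeat_pct simple tandem repeat proportion (\%)
#' @param coding_pct coding-gene proportion (\%), NA to skip
#' @param autonomous_te_pct proportion from the autonomous-library run (\%),
#'   NA to skip
#' @return list(total_repeat_pct, noncharacterized_pct, non_autonomous_pct)
#'   — entries NA where inputs were NA; all half-up at 2 decimals
#' @export
repeatContentSummary <- function(total_te_pct, uncategorized_repeat_pct,
                                 simple_repeat_pct, coding_pct = NA_real_,
                                 autonomous_te_pct = NA_real_) {
  stopifnot(total_te_pct >= 0, total_te_pct <= 100)
  total_repeat <- roundHalfUp(total_te_pct + uncategorized_repeat_pct +
                                simple_repeat_pct, 2)
  nonchar <- if (is.na(coding_pct)) NA_real_
    else roundHalfUp(100 - total_repeat - coding_pct, 2)
  nonaut <- if (is.na(autonomous_te_pct)) NA_real_
    else roundHalfUp(total_te_pct - autonomous_te_pct, 2)
  list(total_repeat_pct = total_repeat, noncharacterized_pct = nonchar,
       non_autonomous_pct = nonaut)
}
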