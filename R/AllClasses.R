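#' Detected candidate repeats with their provenance
#'
#' A set of candidate repeat sequences produced by one or more detectors,
#' carrying per-candidate provenance (detection approach and detector name),
#' optional genomic origin, and optional structural features (terminal repeat
#' kind/length/identity, target-site duplication, poly-A tail).
#'
#' @slot seqs a \link[Biostrings]{DNAStringSet}, names are candidate ids
#' @slot info a \link[S4Vectors]{DataFrame} with one row per candidate:
#'   columns \code{approach} (one of similarity, structural, repetitiveness,
#'   read_based), \code{detector}, \code{contig}, \code{start}, \code{end},
#'   \code{strand} (NA when the candidate has no single genomic origin),
#'   \code{repeat_kind} (direct_pair/inverted_pair/none), \code{repeat_len},
#'   \code{repeat_identity}, \code{tsd}, \code{polyA_len}
#' @export
setClass("TECandidates", representation(seqs = "DNAStringSet", info = "DataFrame"))

.APPROACHES <- c("similarity", "structural", "repetitiveness", "read_based")

.INFO_COLS <- c("approach", "detector", "contig", "start", "end", "strand",
                "repeat_kind", "repeat_len", "repeat_identity", "tsd", "polyA_len")

setValidity("TECandidates", function(object) {
  n <- length(object@seqs)
  if (nrow(object@info) != n) return("info rows must match number of sequences")
  ids <- names(object@seqs)
  if (n > 0 && (is.null(ids) || anyDuplicated(ids) || any(ids == "")))
    return("candidate ids must be non-empty and unique")
  if (n > 0 && any(width(object@seqs) < 1)) return("zero-length candidate sequence")
  miss <- setdiff(.INFO_COLS, colnames(object@info))
  if (length(miss)) return(paste("missing info columns:", paste(miss, collapse = ", ")))
  bad <- !object@info$approach %in% .APPROACHES
  if (n > 0 && any(bad)) return("unknown detection approach")
  TRUE
})

#' Construct a TECandidates set
#'
#' @param seqs DNAStringSet (named) of candidate sequences
#' @param approach detection approach per candidate (recycled if scalar)
#' @param detector detector name per candidate (recycled if scalar)
#' @param contig,start,end,strand optional genomic origin
#' @param repeat_kind,repeat_len,repeat_identity,tsd,polyA_len optional
#'   structural features
#' @return a \linkS4class{TECandidates}
#' @export
TECandidates <- function(seqs, approach, detector,
                         contig = NA_character_, start = NA_integer_,
                         end = NA_integer_, strand = NA_character_,
                         repeat_kind = "none", repeat_len = NA_integer_,
                         repeat_identity = NA_real_, tsd = NA_character_,
                         polyA_len = NA_integer_) {
  n <- length(seqs)
  info <- DataFrame(approach = rep(approach, length.out = n),
                    detector = rep(detector, length.out = n),
                    contig = rep(contig, length.out = n),
                    start = rep(as.integer(start), length.out = n),
                    end = rep(as.integer(end), length.out = n),
                    strand = rep(strand, length.out = n),
                    repeat_kind = rep(repeat_kind, length.out = n),
                    repeat_len = rep(as.integer(repeat_len), length.out = n),
                    repeat_identity = rep(as.numeric(repeat_identity), length.out = n),
                    tsd = rep(tsd, length.out = n),
                    polyA_len = rep(as.integer(polyA_len), length.out = n))
  if (n == 0L) info <- info[integer(0), ]
  rownames(info) <- names(seqs)
  new("TECandidates", seqs = seqs, info = info)
}

emptyCandidates <- function() {
  TECandidates(DNAStringSet(), approach = character(0), detector = character(0))
}

#' @describeIn TECandidates candidate sequences
#' @param x a TECandidates
#' @export
candidateSeqs <- function(x) x@seqs

#' @describeIn TECandidates provenance/feature table
#' @export
candidateInfo <- function(x) x@info

setMethod("length", "TECandidates", function(x) length(x@seqs))

setMethod("[", "TECandidates", function(x, i, j, ..., drop = TRUE) {
  new("TECandidates", seqs = x@seqs[i], info = x@info[i, , drop = FALSE])
})

#' Concatenate candidate sets
#' @param x,... TECandidates objects
#' @export
setMethod("c", "TECandidates", function(x, ...) {
  rest <- list(...)
  seqs <- do.call(c, c(list(x@seqs), lapply(rest, function(y) y@seqs)))
  info <- do.call(rbind, c(list(x@info), lapply(rest, function(y) y@info)))
  new("TECandidates", seqs = seqs, info = info)
})

setMethod("show", "TECandidates", function(object) {
  cat("TECandidates with", length(object), "candidates\n")
  if (length(object) > 0) {
    tb <- table(object@info$approach)
    cat("  approaches:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
    cat("  widths:", min(width(object@seqs)), "-", max(width(object@seqs)), "bp\n")
  }
})

#' A (possibly nested) TE annotation library
#'
#' Sequences plus their Wicker classifications. Three of these, built with
#' the Russian-doll strategy (autonomous \eqn{\subseteq} total
#' \eqn{\subseteq} repeated), drive the nested genome annotation.
#'
#' @slot name library name (e.g. "autonomous", "total", "repeated")
#' @slot seqs named DNAStringSet of library entries
#' @slot classification DataFrame with columns \code{wicker_class}
#'   (I/II/unknown), \code{order}, \code{superfamily}, \code{autonomy}
#' @export
setClass("TELibrary", representation(name = "character", seqs = "DNAStringSet",
                                     classification = "DataFrame"))

.ORDERS <- c("LTR", "LINE", "SINE", "TIR", "Helitron", "MITE", "TRIM", "LARD", "noCat")
.AUTONOMY <- c("autonomous", "non_autonomous", "uncategorized")

setValidity("TELibrary", function(object) {
  n <- length(object@seqs)
  if (nrow(object@classification) != n)
    return("classification rows must match number of sequences")
  if (n > 0 && anyDuplicated(names(object@seqs)))
    return("duplicate ids within a library")
  cls <- object@classification
  need <- c("wicker_class", "order", "superfamily", "autonomy")
  miss <- setdiff(need, colnames(cls))
  if (length(miss)) return(paste("missing classification columns:", paste(miss, collapse = ", ")))
  if (n > 0 && any(!cls$order %in% .ORDERS)) return("unknown TE order")
  if (n > 0 && any(!cls$autonomy %in% .AUTONOMY)) return("unknown autonomy value")
  bad <- cls$order %in% c("SINE", "MITE", "TRIM", "LARD") & cls$autonomy != "non_autonomous"
  if (n > 0 && any(bad))
    return("SINE/MITE/TRIM/LARD entries must be non_autonomous")
  bad2 <- cls$autonomy == "autonomous" & !cls$order %in% c("LTR", "LINE", "TIR", "Helitron")
  if (n > 0 && any(bad2))
    return("autonomous entries must be LTR, LINE, TIR or Helitron")
  TRUE
})

#' Construct a TELibrary
#'
#' @param name library name
#' @param seqs named DNAStringSet
#' @param classification DataFrame (wicker_class, order, superfamily, autonomy)
#' @export
TELibrary <- function(name, seqs, classification) {
  if (is.data.frame(classification)) classification <- DataFrame(classification)
  rownames(classification) <- names(seqs)
  new("TELibrary", name = name, seqs = seqs, classification = classification)
}

#' @describeIn TELibrary library name
#' @param x a TELibrary
#' @export
libraryName <- function(x) x@name

#' @describeIn TELibrary library sequences
#' @export
librarySeqs <- function(x) x@seqs

#' @describeIn TELibrary classification table
#' @export
libraryClassification <- function(x) x@classification

setMethod("length", "TELibrary", function(x) length(x@seqs))

setMethod("[", "TELibrary", function(x, i, j, ..., drop = TRUE) {
  new("TELibrary", name = x@name, seqs = x@seqs[i],
      classification = x@classification[i, , drop = FALSE])
})

setMethod("show", "TELibrary", function(object) {
  cat(sprintf("TELibrary '%s' with %d entries\n", object@name, length(object)))
  if (length(object) > 0) {
    tb <- table(object@classification$order)
    cat("  orders:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
})
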