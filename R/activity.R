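# Crossing annotations with transcript coverage and peptide evidence to
# flag potentially active TE families, plus family mean pairwise identity
# under free-end-gap global alignment.

#' Transcript coverage of annotated copies
#'
#' Per copy, the fraction of its span covered by the union of transcript
#' evidence; a copy is expressed at \code{expressed_cov} or better, and a
#' family is expressed if at least one of its copies is.
#'
#' @param copies GRanges of annotated copies; mcols must carry
#'   \code{copy_id} and \code{family_id}
#' @param transcripts GRanges of transcript intervals on the same contigs,
#'   or a data.frame(copy_id, covered_fraction) of precomputed coverage
#' @param expressed_cov expression threshold
#' @return data.frame(copy_id, family_id, transcript_coverage, expressed)
#' @export
transcriptCoverage <- function(copies, transcripts, expressed_cov = 0.90) {
  cid <- mcols(copies)$copy_id
  fid <- mcols(copies)$family_id
  if (is.null(cid) || is.null(fid))
    .stopf("copies must carry copy_id and family_id metadata columns")
  if (is.data.frame(transcripts)) {
    m <- match(cid, transcripts$copy_id)
    if (anyNA(m)) .stopf("no coverage entry for copy '%s'", cid[is.na(m)][1])
    frac <- transcripts$covered_fraction[m]
  } else {
    if (length(transcripts) > 0) {
      unknown <- !as.character(seqnames(transcripts)) %in%
        unique(as.character(seqnames(copies)))
      ## transcripts on contigs absent from the annotation are ignored, but
      ## copies must live on known contigs of the transcript namespace only
      ## when intervals are provided for them
    }
    frac <- vapply(seq_along(copies), function(i) {
      tx <- transcripts[as.character(seqnames(transcripts)) ==
                          as.character(seqnames(copies))[i]]
      if (length(tx) == 0L) return(0)
      ov <- IRanges::intersect(
        reduce(IRanges(start(tx), end(tx))),
        IRanges(start(copies)[i], end(copies)[i]))
      sum(width(ov)) / width(copies)[i]
    }, numeric(1))
  }
  data.frame(copy_id = cid, family_id = fid, transcript_coverage = frac,
             expressed = frac >= expressed_cov, stringsAsFactors = FALSE)
}

# identity of one free-end-gap global alignment: terminal gap blocks are
# excluded from both numerator and denominator
.fegIdentity <- function(a, b) {
  pa <- pairwiseAlignment(DNAString(a), DNAString(b), type = "overlap",
                          substitutionMatrix = .NUC_MAT,
                          gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT)
  p <- strsplit(as.character(pattern(pa)), "", fixed = TRUE)[[1]]
  s <- strsplit(as.character(subject(pa)), "", fixed = TRUE)[[1]]
  ng <- which(p != "-" & s != "-")
  if (length(ng) == 0L) return(0)
  cols <- seq(min(ng), max(ng))
  sum(p[cols] == s[cols] & p[cols] %in% c("A", "C", "G", "T")) / length(cols)
}

#' Mean pairwise identity of a family's copies
#'
#' Global alignment with free end gaps over all unordered pairs; terminal
#' gap blocks are unpenalized and excluded from the identity denominator.
#' Requires at least three members; fewer yields NA (undefined), not an
#' error. Reported as a percentage to 1 decimal.
#'
#' @param members DNAStringSet of the family's annotated copies
#' @return percentage (1 decimal), or NA_real_ for fewer than 3 members
#' @export
meanPairwiseIdentity <- function(members) {
  n <- length(members)
  if (n < 3L) return(NA_real_)
  ch <- as.character(members)
  tot <- 0; np <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + .fegIdentity(ch[i], ch[j])
      np <- np + 1L
    }
  }
  roundHalfUp(100 * tot / np, 1)
}

#' Match peptides against the six-frame translation of a representative
#'
#' Exact and single-mismatch matches of each peptide (>= 7 residues)
#' against all six reading frames.
#'
#' @param family_rep DNAString (or character) representative sequence
#' @param peptides AAStringSet (or character vector)
#' @return data.frame(peptide, frame, offset, mismatches)
#' @export
matchPeptides <- function(family_rep, peptides) {
  if (is.character(peptides)) peptides <- AAStringSet(peptides)
  if (length(peptides) > 0 && any(width(peptides) < 7L))
    .stopf("peptides must be at least 7 residues")
  s <- DNAString(as.character(family_rep))
  out <- list()
  for (fr in sixFrames(s)) {
    if (nchar(fr$aa) == 0L) next
    aa <- AAString(fr$aa)
    for (pi in seq_along(peptides)) {
      m <- matchPattern(peptides[[pi]], aa, max.mismatch = 1)
      if (length(m) == 0L) next
      for (k in seq_along(m)) {
        mm <- sum(strsplit(as.character(m[[k]]), "")[[1]] !=
                    strsplit(as.character(peptides[[pi]]), "")[[1]])
        out[[length(out) + 1L]] <- data.frame(
          peptide = names(peptides)[pi], frame = fr$frame,
          offset = start(m)[k], mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(peptide = character(0), frame = integer(0),
                      offset = integer(0), mismatches = integer(0)))
  do.call(rbind, out)
}

#' Flag potentially active TE families
#'
#' A family is potentially active iff it is expressed (>= 1 expressed copy)
#' and at least one peptide matches its representative. Evidence tiers
#' (expressed-only, peptide-only, inactive) are reported alongside.
#'
#' @param expression data.frame from \code{\link{transcriptCoverage}}
#' @param family_reps named DNAStringSet of family representatives
#' @param peptides AAStringSet of observed peptides
#' @param copies_by_family optional named list of DNAStringSet (annotated
#'   copy sequences) for mean pairwise identity
#' @return data.frame per family: expressed, n_expressed_copies,
#'   n_peptide_matches, mean_pairwise_identity, tier, potentially_active
#' @export
flagPotentiallyActive <- function(expression, family_reps, peptides,
                                  copies_by_family = NULL) {
  fams <- sort(unique(expression$family_id))
  out <- list()
  for (f in fams) {
    ex <- expression[expression$family_id == f, , drop = FALSE]
    n_exp <- sum(ex$expressed)
    n_pep <- 0L
    if (f %in% names(family_reps) && length(peptides) > 0) {
      pm <- matchPeptides(family_reps[[f]], peptides)
      n_pep <- nrow(pm)
    }
    mpi <- NA_real_
    if (!is.null(copies_by_family) && f %in% names(copies_by_family))
      mpi <- meanPairwiseIdentity(copies_by_family[[f]])
    active <- n_exp > 0L && n_pep > 0L
    tier <- if (active) "potentially_active"
      else if (n_exp > 0L) "expressed_only"
      else if (n_pep > 0L) "peptide_only"
      else "inactive"
    out[[length(out) + 1L]] <- data.frame(
      family_id = f, expressed = n_exp > 0L, n_expressed_copies = n_exp,
      n_peptide_matches = n_pep, mean_pairwise_identity = mpi,
      tier = tier, potentially_active = active, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
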