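# The single alignment engine used throughout the toolkit: exact k-mer seeds
# grouped on near-constant diagonals, followed by banded-window extension with
# Biostrings' affine-gap dynamic programming under one fixed scoring scheme
# (match +2, mismatch -3, gap open 5, gap extend 2). 'N' never matches any
# base: it scores as a mismatch against everything, including itself.

.NUC_ALPHA <- c("A", "C", "G", "T", "N")

nucScoringMatrix <- function(match = 2L, mismatch = -3L) {
  m <- matrix(mismatch, 5, 5, dimnames = list(.NUC_ALPHA, .NUC_ALPHA))
  diag(m)[1:4] <- match
  m["N", "N"] <- mismatch
  m
}

.NUC_MAT <- nucScoringMatrix()
.GAP_OPEN <- 5
.GAP_EXT <- 2

# Alignment statistics for one pairwiseAlignment result. Identity is
# BLAST-style: matches over alignment columns (gap columns count against).
.alnStats <- function(pa) {
  ap <- as.character(pattern(pa))
  as_ <- as.character(subject(pa))
  pc <- strsplit(ap, "", fixed = TRUE)[[1]]
  sc <- strsplit(as_, "", fixed = TRUE)[[1]]
  alnlen <- length(pc)
  matches <- sum(pc == sc & pc %in% c("A", "C", "G", "T"))
  list(score = score(pa), alnlen = alnlen,
       identity = if (alnlen > 0) matches / alnlen else 0,
       q_start = start(pattern(pa)), q_end = end(pattern(pa)),
       s_start = start(subject(pa)), s_end = end(subject(pa)))
}

# Local alignment of two sequences (character or XString) under the package
# scoring scheme. Returns the .alnStats list.
alignPair <- function(a, b, type = "local") {
  pa <- pairwiseAlignment(DNAString(as.character(a)), DNAString(as.character(b)),
                          type = type, substitutionMatrix = .NUC_MAT,
                          gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT)
  .alnStats(pa)
}

# Seed positions of `query` (character) in `subject` (DNAString), one strand.
# Returns data.table(qpos, spos). Seeds containing N are skipped.
.seedPositions <- function(query, subject, k, step = 1L) {
  km <- kmersOf(query, k, step = step)
  if (length(km) == 0L) return(data.table(qpos = integer(0), spos = integer(0)))
  qpos_all <- seq.int(1L, by = step, length.out = length(km))
  ok <- !grepl("N", km, fixed = TRUE)
  km <- km[ok]; qpos_all <- qpos_all[ok]
  if (length(km) == 0L) return(data.table(qpos = integer(0), spos = integer(0)))
  qtab <- data.table(kmer = km, qpos = qpos_all)
  if (length(subject) < 50000L) {
    ## small subject: hash-join on a subject k-mer table beats PDict setup
    sch <- as.character(subject)
    sstarts <- seq_len(nchar(sch) - k + 1L)
    stab <- data.table(kmer = substring(sch, sstarts, sstarts + k - 1L),
                       spos = sstarts)
    hits <- merge(qtab, stab, by = "kmer", allow.cartesian = TRUE,
                  sort = FALSE)[, .(qpos, spos)]
    return(hits)
  }
  uk <- unique(km)
  pd <- PDict(DNAStringSet(uk))
  mi <- startIndex(matchPDict(pd, subject))
  lens <- lengths(mi)
  if (sum(lens) == 0L) return(data.table(qpos = integer(0), spos = integer(0)))
  matched <- data.table(kmer = rep(uk, lens), spos = unlist(mi[lens > 0L]))
  hits <- merge(qtab, matched, by = "kmer", allow.cartesian = TRUE,
                sort = FALSE)[, .(qpos, spos)]
  hits
}

# Exact O(L) scoring of a single-diagonal (gap-free) candidate: the best
# local alignment confined to the diagonal is the maximum-scoring subarray
# of the per-position match/mismatch scores. With an affine gap open of 5
# this equals the unrestricted optimum whenever the true alignment has no
# indels.
.diagonalHit <- function(q, subject_chars, qa, qb, d, slen) {
  if (qa + d < 1L) qa <- 1L - d
  if (qb + d > slen) qb <- slen - d
  if (qb - qa + 1L < 12L) return(NULL)
  qc <- strsplit(substr(q, qa, qb), "", fixed = TRUE)[[1]]
  sc <- subject_chars[(qa + d):(qb + d)]
  eq <- qc == sc & qc != "N"
  sv <- ifelse(eq, 2, -3)
  cs <- cumsum(sv)
  n <- length(sv)
  pre <- c(0, cs[-n])
  pm <- cummin(pre)
  val <- cs - pm
  j <- which.max(val)
  i <- which(pre[seq_len(j)] == pm[j])[1]
  list(score = val[j], q_start = qa + i - 1L, q_end = qa + j - 1L,
       s_start = qa + i - 1L + d, s_end = qa + j - 1L + d,
       identity = mean(eq[i:j]), alnlen = j - i + 1L)
}

# Cluster seeds into candidate loci by diagonal band and positional adjacency.
.seedClusters <- function(seeds, band = 50L, locus_gap = 1000L) {
  if (nrow(seeds) == 0L) return(list())
  seeds[, diagb := (spos - qpos) %/% band]
  setorder(seeds, diagb, spos)
  brk <- c(TRUE, diff(seeds$diagb) != 0L | diff(seeds$spos) > locus_gap)
  seeds[, cl := cumsum(brk)]
  split(seeds, seeds$cl)
}

#' Seed-and-extend local alignments of a query against one subject sequence
#'
#' Exact k-mer seeds anchor candidate loci; each locus is realigned with
#' affine-gap local dynamic programming over a padded window. Hits below
#' \code{min_identity} or shorter than \code{min_len} subject bp are dropped;
#' overlapping hits from adjacent seed clusters are deduplicated, keeping the
#' best score.
#'
#' @param query character or DNAString (the library/candidate sequence)
#' @param subject DNAString (a contig or another sequence)
#' @param min_identity minimum BLAST-style identity of a reported hit
#' @param min_len minimum subject-side alignment span (bp)
#' @param k exact seed length
#' @param min_seeds minimum seeds per cluster before extension is attempted
#' @param both_strands also search the reverse complement of the query
#' @param seed_step sample seeds every \code{seed_step} positions
#' @return data.frame with columns s_start, s_end, strand, identity, score,
#'   q_start, q_end, qcov (query coverage) — subject coordinates are 1-based
#'   inclusive; query coordinates always refer to the forward query
#' @export
seedExtendHits <- function(query, subject, min_identity = 0.8, min_len = 80L,
                           k = 12L, min_seeds = 3L, both_strands = TRUE,
                           seed_step = 1L) {
  query <- as.character(query)
  if (!is(subject, "DNAString")) subject <- DNAString(as.character(subject))
  qlen <- nchar(query)
  slen <- length(subject)
  empty <- data.frame(s_start = integer(0), s_end = integer(0),
                      strand = character(0), identity = numeric(0),
                      score = numeric(0), q_start = integer(0),
                      q_end = integer(0), qcov = numeric(0))
  if (qlen < k || slen < k) return(empty)
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  subject_chars <- NULL
  for (st in strands) {
    q <- if (st == "+") query else rcChar(query)
    seeds <- .seedPositions(q, subject, k, step = seed_step)
    cls <- .seedClusters(seeds)
    for (cl in cls) {
      if (nrow(cl) < min_seeds) next
      pad <- 60L
      ext <- 150L   # margin beyond the seed-covered query region
      qmin <- min(cl$qpos); qmax <- max(cl$qpos) + k - 1L
      qa <- max(1L, qmin - ext); qb <- min(qlen, qmax + ext)
      diags <- cl$spos - cl$qpos
      dtb <- table(diags)
      dmode <- as.integer(names(dtb)[which.max(dtb)])
      onmode <- cl$qpos[diags == dmode]
      mode_span <- max(onmode) - min(onmode) + k
      gapfree <- mode_span >= 0.9 * (qmax - qmin + 1L)
      if (gapfree) {
        ## gap-free cluster: exact diagonal scoring in linear time
        if (is.null(subject_chars))
          subject_chars <- strsplit(as.character(subject), "", fixed = TRUE)[[1]]
        stt <- .diagonalHit(q, subject_chars, qa, qb, dmode, slen)
        if (is.null(stt)) next
        span <- stt$s_end - stt$s_start + 1L
        if (span < min_len || stt$identity < min_identity) next
        qs <- stt$q_start; qe <- stt$q_end
        s1 <- stt$s_start; s2 <- stt$s_end
      } else {
        w1 <- max(1L, min(cl$spos) - (qmin - qa) - pad)
        w2 <- min(slen, max(cl$spos) + k - 1L + (qb - qmax) + pad)
        if (w2 - w1 + 1L < min_len %/% 2L) next
        win <- subseq(subject, w1, w2)
        pa <- pairwiseAlignment(DNAString(substr(q, qa, qb)), win,
                                type = "local",
                                substitutionMatrix = .NUC_MAT,
                                gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT)
        stt <- .alnStats(pa)
        span <- stt$s_end - stt$s_start + 1L
        if (span < min_len || stt$identity < min_identity) next
        qs <- stt$q_start + qa - 1L; qe <- stt$q_end + qa - 1L
        s1 <- w1 + stt$s_start - 1L; s2 <- w1 + stt$s_end - 1L
      }
      if (st == "-") { tmp <- qs; qs <- qlen - qe + 1L; qe <- qlen - tmp + 1L }
      out[[length(out) + 1L]] <- data.frame(
        s_start = s1, s_end = s2,
        strand = st, identity = stt$identity, score = stt$score,
        q_start = qs, q_end = qe, qcov = (qe - qs + 1L) / qlen)
    }
  }
  if (length(out) == 0L) return(empty)
  hits <- do.call(rbind, out)
  .dedupeHits(hits)
}

# Remove near-duplicate hits (same strand, >=50% reciprocal subject overlap),
# keeping the higher score; deterministic ordering.
.dedupeHits <- function(hits) {
  o <- order(-hits$score, hits$s_start, hits$s_end, hits$strand)
  hits <- hits[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i == nrow(hits)) break
    j <- which(keep & seq_len(nrow(hits)) > i)
    if (length(j) == 0L) next
    ov <- pmin(hits$s_end[j], hits$s_end[i]) - pmax(hits$s_start[j], hits$s_start[i]) + 1L
    wi <- hits$s_end[i] - hits$s_start[i] + 1L
    wj <- hits$s_end[j] - hits$s_start[j] + 1L
    dup <- hits$strand[j] == hits$strand[i] & ov > 0.5 * pmin(wi, wj)
    keep[j[dup]] <- FALSE
  }
  res <- hits[keep, , drop = FALSE]
  res[order(res$s_start, res$s_end, res$strand), , drop = FALSE]
}

# Best local alignments between two free-standing sequences, reporting
# coverage of both sides. Used for similarity evidence, family graphs and
# coverage scoring. Returns data.frame of hits plus qcov/scov columns
# (fraction of query/ subject covered by that single hit).
pairHits <- function(a, b, min_identity = 0.8, min_len = 80L, k = 12L,
                     min_seeds = 2L) {
  hits <- seedExtendHits(a, DNAString(as.character(b)),
                         min_identity = min_identity, min_len = min_len,
                         k = k, min_seeds = min_seeds)
  if (nrow(hits) == 0L) return(hits)
  blen <- nchar(as.character(b))
  hits$scov <- (hits$s_end - hits$s_start + 1L) / blen
  hits
}

# Quick shared-kmer fraction between two character sequences (orientation
# insensitive); cheap prefilter before full alignment.
sharedKmerFrac <- function(a, b, k = 12L) {
  ka <- unique(kmersOf(a, k, step = 1L))
  if (length(ka) == 0L) return(0)
  kb <- unique(c(kmersOf(b, k, step = 1L), kmersOf(rcChar(b), k, step = 1L)))
  mean(ka %in% kb)
}
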