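# Structural detection (approach 2): LTR retrotransposon candidates from
# direct-repeat pairs, MITE-like candidates from terminal inverted repeats,
# and SINE candidates from poly-A tails — each anchored by a flanking exact
# target-site duplication (TSD).

# k-mer -> positions table for one contig (character), forward strand.
.kmerPosTable <- function(g, k) {
  n <- nchar(g)
  if (n < k) return(data.table(kmer = character(0), pos = integer(0)))
  starts <- seq_len(n - k + 1L)
  data.table(kmer = substring(g, starts, starts + k - 1L), pos = starts)
}

# exact TSD flanking [s, e]: longest t in [tmin, tmax] with
# g[s-t, s-1] == g[e+1, e+t]; "" if none.
.findTSD <- function(g, s, e, tmin, tmax, forbid_homopolymer = FALSE) {
  n <- nchar(g)
  for (t in seq(tmax, tmin)) {
    if (s - t < 1L || e + t > n) next
    left <- substr(g, s - t, s - 1L)
    right <- substr(g, e + 1L, e + t)
    if (left == right) {
      if (forbid_homopolymer &&
          length(unique(strsplit(left, "", fixed = TRUE)[[1]])) < 2L) next
      return(left)
    }
  }
  ""
}

# TSD search tolerating small boundary slop: local alignment can extend an
# arm a few bases past the true element edge when flanking bases match by
# chance, which would put the TSD probe off target. Offsets are tried in
# order of increasing displacement; the element boundaries consistent with
# the found TSD are returned.
.findTSDSlop <- function(g, s, e, tmin, tmax, max_slop = 3L) {
  n <- nchar(g)
  offs <- seq(-max_slop, max_slop)
  grid <- expand.grid(ds = offs, de = offs)
  grid <- grid[order(abs(grid$ds) + abs(grid$de), grid$ds, grid$de), ]
  ## longest TSD wins over smallest displacement: a chance 1-base arm
  ## extension would otherwise truncate the true TSD to a spurious prefix
  for (t in seq(tmax, tmin)) {
    for (r in seq_len(nrow(grid))) {
      s2 <- s + grid$ds[r]; e2 <- e + grid$de[r]
      if (s2 - t < 1L || e2 + t > n || e2 <= s2) next
      left <- substr(g, s2 - t, s2 - 1L)
      if (left == substr(g, e2 + 1L, e2 + t))
        return(list(tsd = left, s = s2, e = e2))
    }
  }
  NULL
}

# drop candidates overlapping a better-scoring one by > 50% of the smaller
.dedupeCandidateRows <- function(rd) {
  o <- order(-rd$score, rd$start, rd$end)
  rd <- rd[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(rd))
  for (i in seq_len(nrow(rd))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(rd)) > i & rd$contig == rd$contig[i])
    if (!length(j)) next
    ov <- pmin(rd$end[j], rd$end[i]) - pmax(rd$start[j], rd$start[i]) + 1L
    sz <- pmin(rd$end[j] - rd$start[j] + 1L, rd$end[i] - rd$start[i] + 1L)
    keep[j[ov > 0.5 * sz]] <- FALSE
  }
  rd[keep, , drop = FALSE]
}

#' Structural detection of LTR retrotransposon candidates
#'
#' A candidate is a pair of direct repeats (exact-seed anchored, then
#' realigned) with identity at or above \code{min_ltr_identity}, arm length
#' within \code{[min_ltr, max_ltr]}, element span within
#' \code{[min_elem, max_elem]}, flanked by an exact TSD whose length lies in
#' \code{tsd_range}. The emitted span covers the outer LTR edges.
#'
#' @param genome named DNAStringSet
#' @param min_ltr,max_ltr LTR arm length bounds (bp)
#' @param min_elem,max_elem element span bounds (bp)
#' @param min_ltr_identity minimum arm identity
#' @param tsd_range integer length-2 vector of allowed TSD lengths
#' @param k seed length
#' @return a \linkS4class{TECandidates} (approach "structural")
#' @export
detectLTRPairs <- function(genome, min_ltr = 100L, max_ltr = 1000L,
                           min_elem = 1000L, max_elem = 15000L,
                           min_ltr_identity = 0.85, tsd_range = c(4L, 6L),
                           k = 12L) {
  stopifnot(min_elem > 2L * min_ltr)
  rows <- list(); out_seqs <- character(0)
  for (ci in seq_along(genome)) {
    g <- as.character(genome[[ci]])
    n <- nchar(g)
    kp <- .kmerPosTable(g, k)
    kp <- kp[!grepl("N", kmer, fixed = TRUE)]
    kp[, cnt := .N, by = kmer]
    kp <- kp[cnt >= 2L & cnt <= 500L]
    if (nrow(kp) == 0L) next
    setorder(kp, kmer, pos)
    ## distance-limited pair generation: each occurrence against its next
    ## few same-kmer occurrences (vectorized via lagged comparison)
    dmin <- max(200L, min_elem - max_ltr)
    parts <- list()
    for (lag in 1:4) {
      same <- kp$kmer == data.table::shift(kp$kmer, -lag)
      d <- data.table::shift(kp$pos, -lag) - kp$pos
      sel <- !is.na(same) & same & d >= dmin & d <= max_elem
      if (any(sel)) parts[[length(parts) + 1L]] <-
          data.table(p1 = kp$pos[sel], d = d[sel])
    }
    if (length(parts) == 0L) next
    pl <- rbindlist(parts)
    if (nrow(pl) == 0L) next
    pl[, db := d %/% 30L]
    setorder(pl, db, p1)
    brk <- c(TRUE, diff(pl$db) != 0L | diff(pl$p1) > 200L)
    pl[, cl := cumsum(brk)]
    cls <- pl[, .(s_est = min(p1), send = max(p1) + k - 1L,
                  d_med = as.integer(stats::median(d)), ns = .N), by = cl]
    cls <- cls[ns >= 3L]
    for (r in seq_len(nrow(cls))) {
      s_est <- cls$s_est[r]; d_med <- cls$d_med[r]
      w1a <- max(1L, s_est - 50L)
      w1b <- min(n, s_est + max_ltr + 50L)
      w2a <- max(1L, w1a + d_med)
      w2b <- min(n, w1b + d_med)
      if (w2b <= w2a || w1b <= w1a) next
      st <- alignPair(substr(g, w1a, w1b), substr(g, w2a, w2b))
      arm <- min(st$q_end - st$q_start, st$s_end - st$s_start) + 1L
      if (st$identity < min_ltr_identity || arm < min_ltr || arm > max_ltr) next
      s <- w1a + st$q_start - 1L
      e <- w2a + st$s_end - 1L
      span <- e - s + 1L
      if (span < min_elem || span > max_elem) next
      hit <- .findTSDSlop(g, s, e, tsd_range[1], tsd_range[2])
      if (is.null(hit)) next
      tsd <- hit$tsd; s <- hit$s; e <- hit$e
      out_seqs <- c(out_seqs, substr(g, s, e))
      rows[[length(rows) + 1L]] <- data.frame(
        contig = names(genome)[ci], start = s, end = e, score = st$score,
        repeat_len = arm, repeat_identity = st$identity, tsd = tsd,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(emptyCandidates())
  rd <- do.call(rbind, rows)
  rd$seq <- out_seqs
  rd <- .dedupeCandidateRows(rd)
  seqs <- DNAStringSet(rd$seq)
  names(seqs) <- sprintf("ltr_%04d", seq_along(seqs))
  TECandidates(seqs, approach = "structural", detector = "ltr_pair",
               contig = rd$contig, start = rd$start, end = rd$end,
               strand = "+", repeat_kind = "direct_pair",
               repeat_len = rd$repeat_len, repeat_identity = rd$repeat_identity,
               tsd = rd$tsd)
}

#' Structural detection of MITE-like TIR candidates
#'
#' A candidate is a pair of terminal inverted repeats of at least
#' \code{min_tir} bp at 80\% or better arm identity, with element span at
#' most \code{max_elem} bp, flanked by an exact TSD in \code{tsd_range}.
#' Detections from this detector are routed directly to the non-autonomous
#' bin by \code{\link{routeDetections}}.
#'
#' @param genome named DNAStringSet
#' @param min_tir minimum TIR arm length (bp)
#' @param max_elem maximum element span (bp)
#' @param tsd_range allowed TSD length range
#' @param min_tir_identity minimum arm identity
#' @param k seed length (inverted seeds shorter than \code{k + 1} bp need two
#'   seeds to anchor, so arms below 11 bp are not recoverable at the default)
#' @return a \linkS4class{TECandidates} (approach "structural")
#' @export
detectTIRMite <- function(genome, min_tir = 10L, max_elem = 800L,
                          tsd_range = c(2L, 10L), min_tir_identity = 0.8,
                          k = 10L) {
  rows <- list(); out_seqs <- character(0)
  for (ci in seq_along(genome)) {
    g <- as.character(genome[[ci]])
    n <- nchar(g)
    kp <- .kmerPosTable(g, k)
    kp <- kp[!grepl("N", kmer, fixed = TRUE)]
    uk <- unique(kp$kmer)
    rc <- as.character(reverseComplement(DNAStringSet(uk)))
    rcmap <- data.table(kmer = uk, rckmer = rc)
    kp <- merge(kp, rcmap, by = "kmer", sort = FALSE)
    ## pair each position p with positions q of its reverse-complement kmer
    ## downstream within max_elem; bucket the genome into blocks so the join
    ## stays distance-limited, and drop hyper-abundant (low-complexity) kmers
    blk <- 4L * max_elem
    kp[, cnt := .N, by = kmer]
    kp <- kp[cnt <= 200L]
    if (nrow(kp) == 0L) next
    left <- kp[, .(kmer, p = pos, b = pos %/% blk)]
    right0 <- kp[, .(kmer = rckmer, q = pos, b = pos %/% blk)]
    pairs <- rbindlist(list(
      merge(left, right0, by = c("kmer", "b"), allow.cartesian = TRUE),
      merge(left, right0[, .(kmer, q, b = b - 1L)], by = c("kmer", "b"),
            allow.cartesian = TRUE)))
    pairs <- pairs[q > p + k & q <= p + max_elem - k]
    if (nrow(pairs) == 0L) next
    pairs[, cb := (p + q) %/% 20L]
    setorder(pairs, cb, p)
    brk <- c(TRUE, diff(pairs$cb) != 0L | diff(pairs$p) > 100L)
    pairs[, cl := cumsum(brk)]
    cls <- pairs[, .(s_est = min(p), e_est = max(q) + k - 1L, ns = .N), by = cl]
    cls <- cls[ns >= 2L & (e_est - s_est + 1L) <= max_elem]
    for (r in seq_len(nrow(cls))) {
      s_est <- cls$s_est[r]; e_est <- cls$e_est[r]
      wl1 <- max(1L, s_est - 20L); wl2 <- min(n, s_est + 170L)
      wr1 <- max(1L, e_est - 170L); wr2 <- min(n, e_est + 20L)
      if (wl2 >= wr1) { wl2 <- min(wl2, (s_est + e_est) %/% 2L); wr1 <- wl2 + 1L }
      right <- substr(g, wr1, wr2)
      st <- alignPair(substr(g, wl1, wl2), rcChar(right))
      arm <- min(st$q_end - st$q_start, st$s_end - st$s_start) + 1L
      if (st$identity < min_tir_identity || arm < min_tir) next
      s <- wl1 + st$q_start - 1L
      e <- wr1 + nchar(right) - st$s_start
      span <- e - s + 1L
      if (span > max_elem || span < 2L * min_tir + 10L) next
      hit <- .findTSDSlop(g, s, e, tsd_range[1], tsd_range[2])
      if (is.null(hit)) next
      tsd <- hit$tsd; s <- hit$s; e <- hit$e
      out_seqs <- c(out_seqs, substr(g, s, e))
      rows[[length(rows) + 1L]] <- data.frame(
        contig = names(genome)[ci], start = s, end = e, score = st$score,
        repeat_len = arm, repeat_identity = st$identity, tsd = tsd,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(emptyCandidates())
  rd <- do.call(rbind, rows)
  rd$seq <- out_seqs
  rd <- .dedupeCandidateRows(rd)
  seqs <- DNAStringSet(rd$seq)
  names(seqs) <- sprintf("mite_%04d", seq_along(seqs))
  TECandidates(seqs, approach = "structural", detector = "tir_mite",
               contig = rd$contig, start = rd$start, end = rd$end,
               strand = "+", repeat_kind = "inverted_pair",
               repeat_len = rd$repeat_len, repeat_identity = rd$repeat_identity,
               tsd = rd$tsd)
}

# SINE scan on one strand of one contig string; returns candidate rows with
# coordinates on that strand.
.sineScanOneStrand <- function(g, len_range, min_tail, tsd_range) {
  rows <- list()
  n <- nchar(g)
  m <- gregexpr(sprintf("A{%d,}", min_tail), g)[[1]]
  if (m[1] == -1L) return(rows)
  run_start <- as.integer(m)
  run_len <- attr(m, "match.length")
  for (i in seq_along(run_start)) {
    e <- run_start[i] + run_len[i] - 1L
    found <- FALSE
    for (t in seq(tsd_range[2], tsd_range[1])) {
      if (e + t > n) next
      pat <- substr(g, e + 1L, e + t)
      if (length(unique(strsplit(pat, "", fixed = TRUE)[[1]])) < 2L) next
      wa <- max(1L, e - len_range[2] + 1L - t)
      wb <- e - len_range[1] + 1L
      if (wb <= wa) next
      win <- substr(g, wa, wb)
      hit <- gregexpr(pat, win, fixed = TRUE)[[1]]
      if (hit[1] == -1L) next
      for (h in as.integer(hit)) {
        s <- wa + h - 1L + t   # element starts right after the left TSD
        len <- e - s + 1L
        if (len < len_range[1] || len > len_range[2]) next
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, end = e, tsd = pat, polyA_len = run_len[i],
          score = run_len[i] + 2L * t, stringsAsFactors = FALSE)
        found <- TRUE
        break
      }
      if (found) break
    }
  }
  rows
}

#' Structural detection of SINE candidates
#'
#' A candidate is a span within \code{len_range} ending in a poly-A tail of
#' at least \code{min_tail} bp (poly-T head on the minus strand), flanked by
#' an exact TSD. SINE-detector output is routed directly to the
#' non-autonomous bin.
#'
#' @param genome named DNAStringSet
#' @param len_range element length bounds (bp)
#' @param min_tail minimum poly-A run (bp)
#' @param tsd_range allowed TSD length range
#' @return a \linkS4class{TECandidates} (approach "structural")
#' @export
detectSINE <- function(genome, len_range = c(80L, 600L), min_tail = 8L,
                       tsd_range = c(7L, 10L)) {
  rows <- list(); out_seqs <- character(0)
  for (ci in seq_along(genome)) {
    g <- as.character(genome[[ci]])
    n <- nchar(g)
    for (strand_ in c("+", "-")) {
      gg <- if (strand_ == "+") g else rcChar(g)
      found <- .sineScanOneStrand(gg, len_range, min_tail, tsd_range)
      for (f in found) {
        s <- f$start; e <- f$end
        if (strand_ == "-") { s2 <- n - e + 1L; e2 <- n - f$start + 1L
        } else { s2 <- s; e2 <- e }
        out_seqs <- c(out_seqs, substr(g, s2, e2))
        ## the TSD is reported in plus-strand orientation
        tsd_plus <- if (strand_ == "-") rcChar(f$tsd) else f$tsd
        rows[[length(rows) + 1L]] <- data.frame(
          contig = names(genome)[ci], start = s2, end = e2, strand = strand_,
          tsd = tsd_plus, polyA_len = f$polyA_len, score = f$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(emptyCandidates())
  rd <- do.call(rbind, rows)
  rd$seq <- out_seqs
  rd <- .dedupeCandidateRows(rd)
  seqs <- DNAStringSet(rd$seq)
  names(seqs) <- sprintf("sine_%04d", seq_along(seqs))
  TECandidates(seqs, approach = "structural", detector = "sine_finder",
               contig = rd$contig, start = rd$start, end = rd$end,
               strand = rd$strand, repeat_kind = "none",
               tsd = rd$tsd, polyA_len = rd$polyA_len)
}
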