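# Independent oracles used by the tests. These deliberately re-derive
# quantities with naive algorithms (per-base masks, quadratic dynamic
# programming, all-pairs scans) so that the package's optimized paths are
# checked against something that cannot share their bugs.

oracle_rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

# fraction of identical positions between equal-length strings
oracle_hamming_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}

# union length of a set of [start, end] integer intervals via a boolean mask
oracle_union_length <- function(starts, ends, n) {
  mask <- logical(n)
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  sum(mask)
}

# all-pairs exact containment scan (either orientation): returns ids that
# are substrings of a strictly longer sequence, or duplicates of an
# equal-length sequence with a smaller id
oracle_containment_removed <- function(seqs) {
  ids <- names(seqs)
  ch <- as.character(seqs)
  removed <- character(0)
  for (i in seq_along(ch)) {
    for (j in seq_along(ch)) {
      if (i == j) next
      longer <- nchar(ch[j]) > nchar(ch[i]) ||
        (nchar(ch[j]) == nchar(ch[i]) && ids[j] < ids[i])
      if (!longer) next
      if (grepl(ch[i], ch[j], fixed = TRUE) ||
          grepl(oracle_revcomp(ch[i]), ch[j], fixed = TRUE)) {
        removed <- c(removed, ids[i])
        break
      }
    }
  }
  removed
}

# quadratic-time global alignment with free end gaps (match +2, mismatch -3,
# linear gap -2); returns identity over columns excluding terminal gap
# blocks, computed straight from the traceback
oracle_feg_identity <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)   # free leading gaps: first row/col zero
  P <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 up (gap in b), 3 left (gap in a)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- S[i, j] + ifelse(A[i] == B[j], 2, -3)
      u <- S[i, j + 1] - 2
      l <- S[i + 1, j] - 2
      best <- max(d, u, l)
      S[i + 1, j + 1] <- best
      P[i + 1, j + 1] <- which.max(c(d, u, l))
    }
  }
  ## free trailing gaps: best cell on last row or column
  lastcol <- S[, m + 1]; lastrow <- S[n + 1, ]
  if (max(lastcol) >= max(lastrow)) { i <- which.max(lastcol); j <- m + 1 }
  else { i <- n + 1; j <- which.max(lastrow) }
  cols <- character(0)
  while (i > 1 && j > 1) {
    mv <- P[i, j]
    if (mv == 1L) { cols <- c(ifelse(A[i - 1] == B[j - 1], "M", "X"), cols); i <- i - 1; j <- j - 1 }
    else if (mv == 2L) { cols <- c("G", cols); i <- i - 1 }
    else { cols <- c("G", cols); j <- j - 1 }
  }
  if (length(cols) == 0L) return(0)
  sum(cols == "M") / length(cols)
}

# naive ORF scan: longest stop-free codon run (in nt) over all 6 frames,
# using a hand-written codon table restricted to stops
oracle_max_orf_nt <- function(x) {
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (s in c(x, oracle_revcomp(x))) {
    for (f in 1:3) {
      n <- nchar(s)
      codons <- substring(s, seq(f, n - 2, by = 3), seq(f + 2, n, by = 3))
      isstop <- codons %in% stops
      run <- 0L
      for (v in isstop) {
        if (v) run <- 0L else { run <- run + 1L; best <- max(best, run * 3L) }
      }
    }
  }
  best
}

# naive translation (frame 1) with a hand-written codon table
oracle_translate <- function(nt) {
  tab <- c(TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
           ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
           TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
           ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
           TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
           AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
           TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
           AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  n <- nchar(nt) %/% 3 * 3
  paste(tab[substring(nt, seq(1, n - 2, 3), seq(3, n, 3))], collapse = "")
}
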