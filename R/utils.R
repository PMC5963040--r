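# Shared low-level helpers. Coordinates throughout the package are 1-based
# inclusive (IRanges convention); BED emission converts on write.

#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even; printed percentages in TE
#' annotation reports conventionally round half up. A tiny epsilon guards
#' against binary-representation artefacts (e.g. 74.5 stored as 74.49999...).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Uniform i.i.d. DNA of length n (character scalar). Caller manages the seed.
randDNA <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Reverse complement of a character scalar.
rcChar <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

# All k-mers of a character scalar as a character vector (empty if too short).
kmersOf <- function(x, k, step = 1L) {
  n <- nchar(x)
  if (n < k) return(character(0))
  starts <- seq.int(1L, n - k + 1L, by = step)
  substring(x, starts, starts + k - 1L)
}

# Six-frame translations of a DNAString. Returns a list of entries
# (frame, aa, offset) where frame is 1,2,3 on the plus strand and -1,-2,-3 on
# the minus strand, and `offset` maps aa position j to the 1-based start of
# its codon on the PLUS strand: for frame f>0, nt = offset + 3*(j-1); for
# f<0 the codon occupies [L - (offset + 3*j - 1) + 1, L - (offset + 3*(j-1)) + 1]
# counted from the plus strand.
sixFrames <- function(dna) {
  if (is.character(dna)) dna <- DNAString(dna)
  rc <- reverseComplement(dna)
  L <- length(dna)
  out <- vector("list", 6L)
  i <- 1L
  for (f in 1:3) {
    len <- ((L - f + 1L) %/% 3L) * 3L
    aa <- if (len >= 3L)
      as.character(suppressWarnings(translate(subseq(dna, f, f + len - 1L),
                                              if.fuzzy.codon = "X")))
    else ""
    out[[i]] <- list(frame = f, aa = aa, offset = f)
    i <- i + 1L
  }
  for (f in 1:3) {
    len <- ((L - f + 1L) %/% 3L) * 3L
    aa <- if (len >= 3L)
      as.character(suppressWarnings(translate(subseq(rc, f, f + len - 1L),
                                              if.fuzzy.codon = "X")))
    else ""
    out[[i]] <- list(frame = -f, aa = aa, offset = f)
    i <- i + 1L
  }
  out
}

# Map an amino-acid range [a1, a2] in frame f (sixFrames convention) back to
# plus-strand nucleotide coordinates on a sequence of length L.
aaRangeToNt <- function(a1, a2, frame, L) {
  f <- abs(frame)
  nt1 <- f + 3L * (a1 - 1L)
  nt2 <- f + 3L * a2 - 1L
  if (frame > 0) c(nt1, nt2) else c(L - nt2 + 1L, L - nt1 + 1L)
}

# Maximal stop-free amino-acid runs of length >= min_aa in a translation.
# Returns data.frame(aa_start, aa_end) in aa coordinates of that frame.
stopFreeRuns <- function(aa, min_aa) {
  if (nchar(aa) == 0L) return(data.frame(aa_start = integer(0), aa_end = integer(0)))
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  stops <- c(0L, which(ch == "*"), length(ch) + 1L)
  s <- stops[-length(stops)] + 1L
  e <- stops[-1] - 1L
  keep <- (e - s + 1L) >= min_aa
  data.frame(aa_start = s[keep], aa_end = e[keep])
}

# Open reading frames (stop-free runs) of >= min_nt nucleotides across all six
# frames. Returns data.frame(frame, start, end, aa) with plus-strand nt coords.
findORFs <- function(dna, min_nt = 300L) {
  if (is.character(dna)) dna <- DNAString(dna)
  L <- length(dna)
  res <- list()
  for (fr in sixFrames(dna)) {
    runs <- stopFreeRuns(fr$aa, ceiling(min_nt / 3))
    if (nrow(runs) == 0L) next
    for (j in seq_len(nrow(runs))) {
      nt <- aaRangeToNt(runs$aa_start[j], runs$aa_end[j], fr$frame, L)
      res[[length(res) + 1L]] <- data.frame(
        frame = fr$frame, start = nt[1], end = nt[2],
        aa = substr(fr$aa, runs$aa_start[j], runs$aa_end[j]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L)
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), aa = character(0)))
  do.call(rbind, res)
}

# Longest terminal homopolymer-A tail (allowing it to end within `window` bp
# of the 3' end); returns its length, 0 if below min_run.
polyATail <- function(x, min_run = 8L, window = 30L) {
  n <- nchar(x)
  tailseq <- substr(x, max(1L, n - window + 1L), n)
  m <- gregexpr("A+", tailseq)[[1]]
  if (m[1] == -1L) return(0L)
  len <- attr(m, "match.length")
  best <- max(len)
  if (best >= min_run) best else 0L
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
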