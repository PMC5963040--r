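# Repetitiveness-based detection (approach 3) and read-based detection
# (approach 4): genome-wide repeated k-mer mining with consensus building,
# and greedy k-mer assembly of high-abundance k-mers from unassembled reads.

# canonical form of a set of kmers (lexicographic min of kmer / revcomp)
.canonical <- function(kmers) {
  rc <- as.character(reverseComplement(DNAStringSet(kmers)))
  pmin(kmers, rc)
}

# union coverage of the shorter sequence given pairHits() output
.coverageOfShorter <- function(hits, la, lb) {
  if (nrow(hits) == 0L) return(0)
  if (la <= lb) {
    ir <- reduce(IRanges(hits$q_start, hits$q_end))
    sum(width(ir)) / la
  } else {
    ir <- reduce(IRanges(hits$s_start, hits$s_end))
    sum(width(ir)) / lb
  }
}

# majority-vote consensus of cluster members over the exemplar's columns
.majorityConsensus <- function(exemplar, members) {
  ex <- as.character(exemplar)
  L <- nchar(ex)
  exch <- strsplit(ex, "", fixed = TRUE)[[1]]
  votes <- matrix(0L, nrow = 4, ncol = L, dimnames = list(c("A","C","G","T"), NULL))
  ok <- exch %in% rownames(votes)
  votes[cbind(match(exch[ok], rownames(votes)), which(ok))] <- 1L
  for (m in members) {
    mm <- as.character(m)
    st <- alignPair(mm, ex)
    if (st$alnlen == 0L) next
    pa <- pairwiseAlignment(DNAString(mm), DNAString(ex), type = "local",
                            substitutionMatrix = .NUC_MAT,
                            gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT)
    pch <- strsplit(as.character(pattern(pa)), "", fixed = TRUE)[[1]]
    sch <- strsplit(as.character(subject(pa)), "", fixed = TRUE)[[1]]
    j <- start(subject(pa)) - 1L
    for (col in seq_along(sch)) {
      if (sch[col] != "-") {
        j <- j + 1L
        if (pch[col] %in% rownames(votes)) {
          r <- match(pch[col], rownames(votes))
          votes[r, j] <- votes[r, j] + 1L
        }
      }
    }
  }
  picks <- apply(votes, 2, function(v) {
    w <- which(v == max(v))
    if (length(w) > 1L) NA_integer_ else w
  })
  out <- exch
  sel <- !is.na(picks)
  out[sel] <- rownames(votes)[picks[sel]]
  paste(out, collapse = "")
}

#' Repetitiveness-based consensus detection
#'
#' k-mers occurring at least \code{min_copies} times (both strands pooled
#' via canonical form) seed repeat instances: covered positions are merged
#' into maximal segments, segments are clustered greedily against exemplars
#' at 80\% identity over 80\% of the shorter sequence, and a majority-vote
#' consensus is emitted per cluster.
#'
#' @param genome named DNAStringSet
#' @param k k-mer size (12--32)
#' @param min_copies minimum genome-wide k-mer multiplicity
#' @param min_seg minimum repeat segment length retained (bp)
#' @param merge_gap segments closer than this are merged (bridges point
#'   mutations that break exact k-mer identity)
#' @param max_members_consensus members used per consensus vote
#' @return a \linkS4class{TECandidates} (approach "repetitiveness")
#' @export
detectRepetitive <- function(genome, k = 16L, min_copies = 3L,
                             min_seg = 100L, merge_gap = 60L,
                             max_members_consensus = 12L) {
  stopifnot(k >= 12L, k <= 32L)
  if (all(width(genome) < k)) return(emptyCandidates())
  tabs <- list()
  for (ci in seq_along(genome)) {
    t <- .kmerPosTable(as.character(genome[[ci]]), k)
    if (nrow(t) == 0L) next
    t[, contig := names(genome)[ci]]
    tabs[[length(tabs) + 1L]] <- t
  }
  kp <- rbindlist(tabs)
  kp <- kp[!grepl("N", kmer, fixed = TRUE)]
  uk <- unique(kp$kmer)
  can <- data.table(kmer = uk, cmer = .canonical(uk))
  kp <- merge(kp, can, by = "kmer", sort = FALSE)
  cnt <- kp[, .(n = .N), by = cmer]
  high <- cnt[n >= min_copies, cmer]
  if (length(high) == 0L) return(emptyCandidates())
  hp <- kp[cmer %in% high]
  ## merge covered positions into repeat segments per contig
  inst_seqs <- character(0); inst_loc <- list()
  for (ci in unique(hp$contig)) {
    pos <- sort(hp[contig == ci, pos])
    ir <- reduce(IRanges(pos, pos + k - 1L), min.gapwidth = merge_gap)
    ir <- ir[width(ir) >= min_seg]
    if (length(ir) == 0L) next
    g <- genome[[ci]]
    for (i in seq_along(ir)) {
      inst_seqs <- c(inst_seqs, as.character(subseq(g, start(ir)[i], end(ir)[i])))
      inst_loc[[length(inst_loc) + 1L]] <- data.frame(
        contig = ci, start = start(ir)[i], end = end(ir)[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(inst_seqs) == 0L) return(emptyCandidates())
  loc <- do.call(rbind, inst_loc)
  ## greedy clustering against exemplars (longest first)
  o <- order(-nchar(inst_seqs), loc$contig, loc$start)
  inst_seqs <- inst_seqs[o]; loc <- loc[o, , drop = FALSE]
  exemplar_idx <- integer(0)
  members <- list()
  assign_of <- integer(length(inst_seqs))
  for (i in seq_along(inst_seqs)) {
    placed <- FALSE
    for (e in seq_along(exemplar_idx)) {
      ex <- inst_seqs[exemplar_idx[e]]
      if (sharedKmerFrac(inst_seqs[i], ex, k = 12L) < 0.15) next
      hits <- pairHits(inst_seqs[i], ex, min_identity = 0.8, min_len = 50L)
      if (.coverageOfShorter(hits, nchar(inst_seqs[i]), nchar(ex)) >= 0.8) {
        members[[e]] <- c(members[[e]], i)
        assign_of[i] <- e
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      exemplar_idx <- c(exemplar_idx, i)
      members[[length(exemplar_idx)]] <- integer(0)
      assign_of[i] <- length(exemplar_idx)
    }
  }
  cons <- character(0); rows <- list()
  for (e in seq_along(exemplar_idx)) {
    ei <- exemplar_idx[e]
    mem <- head(members[[e]], max_members_consensus)
    cs <- if (length(mem) == 0L) inst_seqs[ei]
          else .majorityConsensus(DNAString(inst_seqs[ei]),
                                  lapply(inst_seqs[mem], DNAString))
    cons <- c(cons, cs)
    rows[[length(rows) + 1L]] <- loc[ei, , drop = FALSE]
  }
  rd <- do.call(rbind, rows)
  seqs <- DNAStringSet(cons)
  names(seqs) <- sprintf("rep_%04d", seq_along(seqs))
  TECandidates(seqs, approach = "repetitiveness", detector = "kmer_consensus",
               contig = rd$contig, start = rd$start, end = rd$end, strand = "+")
}

# k-mer count table (canonical) from a DNAStringSet of reads
.readKmerCounts <- function(reads, k) {
  rc <- as.character(reads)
  wmax <- max(nchar(rc))
  parts <- list()
  for (i in seq_len(max(0L, wmax - k + 1L))) {
    s <- substr(rc, i, i + k - 1L)
    s <- s[nchar(s) == k]
    if (length(s)) parts[[length(parts) + 1L]] <- s
  }
  if (length(parts) == 0L)
    return(data.table(cmer = character(0), n = integer(0)))
  km <- data.table(kmer = unlist(parts))
  km <- km[!grepl("N", kmer, fixed = TRUE)]
  cnt <- km[, .(n0 = .N), by = kmer]
  cnt[, cmer := .canonical(kmer)]
  cnt[, .(n = sum(n0)), by = cmer]
}

#' Read-based repeat detection by high-abundance k-mer assembly
#'
#' Canonical k-mer counts are computed from the reads; the modal non-error
#' abundance is estimated as the histogram mode above 1; k-mers with count
#' at least \code{abundance_factor} times the mode are retained and greedily
#' assembled by unique (k-1)-overlap extension into contigs.
#'
#' @param reads named DNAStringSet of reads
#' @param k k-mer size (must not exceed the read length)
#' @param abundance_factor fold-over-modal abundance threshold
#' @param min_contig minimum assembled contig length emitted (bp); the
#'   500 bp curation filter applies downstream regardless
#' @return a \linkS4class{TECandidates} (approach "read_based")
#' @export
detectFromReads <- function(reads, k = 21L, abundance_factor = 5,
                            min_contig = 100L) {
  if (length(reads) == 0L) .stopf("no reads supplied")
  if (k > min(width(reads))) .stopf("k exceeds the read length")
  cnt <- .readKmerCounts(reads, k)
  cnt <- cnt[n > 1L]
  if (nrow(cnt) == 0L) return(emptyCandidates())
  tb <- cnt[, .N, by = n]
  setorder(tb, -N, n)
  mode_n <- tb$n[1]
  thr <- abundance_factor * mode_n
  kept <- cnt[n >= thr, cmer]
  if (length(kept) == 0L) return(emptyCandidates())
  oriented <- unique(c(kept, as.character(reverseComplement(DNAStringSet(kept)))))
  kset <- new.env(parent = emptyenv(), size = length(oriented) * 2L)
  for (x in oriented) assign(x, TRUE, envir = kset)
  visited <- new.env(parent = emptyenv(), size = length(oriented) * 2L)
  succ <- function(x) {
    suf <- substr(x, 2L, k)
    nx <- paste0(suf, c("A", "C", "G", "T"))
    nx[vapply(nx, function(y) exists(y, envir = kset, inherits = FALSE), logical(1))]
  }
  pred <- function(x) {
    pre <- substr(x, 1L, k - 1L)
    nx <- paste0(c("A", "C", "G", "T"), pre)
    nx[vapply(nx, function(y) exists(y, envir = kset, inherits = FALSE), logical(1))]
  }
  mark <- function(x) {
    assign(x, TRUE, envir = visited)
    assign(rcChar(x), TRUE, envir = visited)
  }
  seen <- function(x) exists(x, envir = visited, inherits = FALSE)
  contigs <- character(0)
  for (seed_kmer in sort(oriented)) {
    if (seen(seed_kmer)) next
    mark(seed_kmer)
    ctg <- seed_kmer
    cur <- seed_kmer
    repeat {
      nx <- succ(cur)
      nx <- nx[!vapply(nx, seen, logical(1))]
      if (length(nx) != 1L) break
      cur <- nx
      mark(cur)
      ctg <- paste0(ctg, substr(cur, k, k))
    }
    cur <- seed_kmer
    repeat {
      nx <- pred(cur)
      nx <- nx[!vapply(nx, seen, logical(1))]
      if (length(nx) != 1L) break
      cur <- nx
      mark(cur)
      ctg <- paste0(substr(cur, 1L, 1L), ctg)
    }
    if (nchar(ctg) >= min_contig) contigs <- c(contigs, ctg)
  }
  if (length(contigs) == 0L) return(emptyCandidates())
  seqs <- DNAStringSet(contigs)
  names(seqs) <- sprintf("read_%04d", seq_along(seqs))
  TECandidates(seqs, approach = "read_based", detector = "kmer_assembly")
}
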