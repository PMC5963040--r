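# Detector tests run on compact planted worlds (zero divergence unless the
# case is about divergence) so every expectation can be checked against the
# planted truth.

test_that("nucleotide similarity detection recovers planted copies at their truth intervals", {
  w <- small_world()
  det <- detectSimilarityNT(w$genome, w$databank)
  expect_true(all(candidateInfo(det)$approach == "similarity"))
  tr <- w$truth[S4Vectors::mcols(w$truth)$family_id == "copia1"]
  info <- candidateInfo(det)
  for (i in seq_along(tr)) {
    hit <- which(info$contig == as.character(GenomicRanges::seqnames(tr))[i] &
                   abs(info$start - GenomicRanges::start(tr)[i]) <= 10 &
                   abs(info$end - GenomicRanges::end(tr)[i]) <= 10)
    expect_gte(length(hit), 1)
  }
})

test_that("similarity detection with an empty library returns an empty set", {
  w <- small_world()
  det <- detectSimilarityNT(w$genome, Biostrings::DNAStringSet())
  expect_equal(length(det), 0)
})

test_that("similarity detection drops copies beyond the identity floor", {
  tm <- teTemplateCatalog()["copia1"]
  pc <- plantCopies(100000L, tm, copies_per_family = 2L, divergence = 0.30,
                    seed = 77L)
  db <- referenceDatabank(tm, seed = 77L)
  det <- detectSimilarityNT(pc$genome, db, min_identity = 0.8,
                            min_hit_len = 500L)
  ## a 30%-divergent copy cannot sustain a long 80%-identity alignment
  expect_equal(length(det), 0)
})

test_that("protein-domain detection finds planted ORFs and flags strand", {
  w <- small_world()
  det <- detectSimilarityProt(w$genome)
  expect_gt(length(det), 0)
  info <- candidateInfo(det)
  ## every autonomous planted copy (here: copia, mariner, hat) should be
  ## overlapped by some domain hit
  aut <- w$truth[S4Vectors::mcols(w$truth)$order %in% c("LTR", "TIR")]
  for (i in seq_along(aut)) {
    ov <- which(info$contig == as.character(GenomicRanges::seqnames(aut))[i] &
                  info$start <= GenomicRanges::end(aut)[i] &
                  info$end >= GenomicRanges::start(aut)[i])
    expect_gte(length(ov), 1)
    ## reported strand matches the planted strand of that copy
    expect_true(as.character(GenomicRanges::strand(aut))[i] %in% info$strand[ov])
  }
})

test_that("protein-domain detection stays silent on random background", {
  g <- Biostrings::DNAStringSet(c(bg = oracle_rand_dna(50000, seed = 21)))
  expect_equal(length(detectSimilarityProt(g)), 0)
})

test_that("LTR pair detection reports the element span of a planted copy", {
  w <- small_world()
  det <- detectLTRPairs(w$genome)
  info <- candidateInfo(det)
  tr <- w$truth[S4Vectors::mcols(w$truth)$family_id == "copia1"]
  ## boundary placement is ambiguous by a base or two when element-edge
  ## bases coincide with TSD bases, so spans are checked to +/- 2 bp
  for (i in seq_along(tr)) {
    hit <- which(info$contig == as.character(GenomicRanges::seqnames(tr))[i] &
                   abs(info$start - GenomicRanges::start(tr)[i]) <= 2 &
                   abs(info$end - GenomicRanges::end(tr)[i]) <= 2)
    expect_equal(length(hit), 1)
    expect_equal(info$repeat_kind[hit], "direct_pair")
    expect_gte(info$repeat_identity[hit], 0.85)
  }
})

test_that("LTR pair detection is empty on background and rejects degenerate arms", {
  g <- Biostrings::DNAStringSet(c(bg = oracle_rand_dna(120000, seed = 22)))
  expect_equal(length(detectLTRPairs(g)), 0)
  ## 15% per-copy divergence drives arm-vs-arm identity to ~72%
  tm <- teTemplateCatalog()["copia1"]
  pc <- plantCopies(100000L, tm, copies_per_family = 2L, divergence = 0.15,
                    seed = 23L)
  expect_equal(length(detectLTRPairs(pc$genome, min_ltr_identity = 0.85)), 0)
})

test_that("TIR/MITE detection finds planted MITEs and respects the size cap", {
  w <- small_world()
  det <- detectTIRMite(w$genome)
  info <- candidateInfo(det)
  tr <- w$truth[S4Vectors::mcols(w$truth)$family_id == "mite1"]
  for (i in seq_along(tr)) {
    hit <- which(info$contig == as.character(GenomicRanges::seqnames(tr))[i] &
                   abs(info$start - GenomicRanges::start(tr)[i]) <= 2 &
                   abs(info$end - GenomicRanges::end(tr)[i]) <= 2)
    expect_equal(length(hit), 1)
    expect_equal(info$repeat_kind[hit], "inverted_pair")
  }
  ## mariner copies (1.6 kb) carry valid TIRs but exceed max_elem = 800
  mar <- w$truth[S4Vectors::mcols(w$truth)$family_id == "mariner1"]
  for (i in seq_along(mar)) {
    ov <- which(info$contig == as.character(GenomicRanges::seqnames(mar))[i] &
                  info$start >= GenomicRanges::start(mar)[i] - 5 &
                  info$end <= GenomicRanges::end(mar)[i] + 5 &
                  (info$end - info$start + 1) > 800)
    expect_equal(length(ov), 0)
  }
})

test_that("SINE detection needs both the tail and an exact TSD", {
  w <- small_world()
  det <- detectSINE(w$genome)
  info <- candidateInfo(det)
  tr <- w$truth[S4Vectors::mcols(w$truth)$family_id == "sine1"]
  for (i in seq_along(tr)) {
    hit <- which(info$contig == as.character(GenomicRanges::seqnames(tr))[i] &
                   info$start == GenomicRanges::start(tr)[i] &
                   info$end == GenomicRanges::end(tr)[i])
    expect_equal(length(hit), 1)
    expect_identical(info$tsd[hit], S4Vectors::mcols(tr)$tsd[i])
  }
  ## a bare poly-A run without a flanking TSD is not a candidate
  g <- Biostrings::DNAStringSet(c(bg = paste0(
    oracle_rand_dna(3000, seed = 31), strrep("A", 15),
    oracle_rand_dna(3000, seed = 32))))
  expect_equal(length(detectSINE(g)), 0)
})

test_that("repetitiveness detection builds a faithful consensus from planted copies", {
  tpl <- oracle_rand_dna(1000, seed = 41)
  set.seed(42)
  pieces <- character(0)
  for (i in 1:5) pieces <- c(pieces, oracle_rand_dna(30000, seed = 42 + i), tpl)
  g <- Biostrings::DNAStringSet(c(c1 = paste(c(pieces,
    oracle_rand_dna(30000, seed = 50)), collapse = "")))
  det <- detectRepetitive(g, min_copies = 3L)
  expect_gte(length(det), 1)
  covs <- vapply(as.character(candidateSeqs(det)), function(s)
    coverageScore(s, tpl, min_identity = 0.95), numeric(1))
  expect_gte(max(covs), 0.95)
})

test_that("repetitiveness detection returns nothing on unique sequence", {
  g <- Biostrings::DNAStringSet(c(c1 = oracle_rand_dna(150000, seed = 51)))
  expect_equal(length(detectRepetitive(g)), 0)
})

test_that("two unrelated planted families give consensi matching only their own template", {
  t1 <- oracle_rand_dna(800, seed = 61)
  t2 <- oracle_rand_dna(1200, seed = 62)
  parts <- character(0)
  for (i in 1:4) parts <- c(parts, oracle_rand_dna(15000, seed = 62 + i), t1,
                            oracle_rand_dna(15000, seed = 70 + i), t2)
  g <- Biostrings::DNAStringSet(c(c1 = paste(parts, collapse = "")))
  det <- detectRepetitive(g, min_copies = 3L)
  expect_gte(length(det), 2)
  cov1 <- vapply(as.character(candidateSeqs(det)), coverageScore, numeric(1),
                 reference = t1)
  cov2 <- vapply(as.character(candidateSeqs(det)), coverageScore, numeric(1),
                 reference = t2)
  expect_gte(max(cov1), 0.9)
  expect_gte(max(cov2), 0.9)
  ## no consensus matches both templates
  expect_true(all(pmin(cov1, cov2) < 0.1))
})

test_that("read-based detection assembles a high-abundance repeat", {
  tpl <- oracle_rand_dna(1000, seed = 81)
  parts <- character(0)
  for (i in 1:50) parts <- c(parts, oracle_rand_dna(1000, seed = 81 + i), tpl)
  g <- Biostrings::DNAStringSet(c(c1 = paste(parts, collapse = "")))
  reads <- simulateReads(g, read_len = 100L, depth = 20, seed = 82L)
  det <- detectFromReads(reads, k = 21L, abundance_factor = 5)
  long <- candidateSeqs(det)[Biostrings::width(candidateSeqs(det)) >= 500]
  expect_gte(length(long), 1)
  best <- vapply(as.character(long), function(s)
    coverageScore(s, tpl, min_identity = 0.9), numeric(1))
  expect_gte(max(best), 0.5)
  ## determinism
  det2 <- detectFromReads(reads, k = 21L, abundance_factor = 5)
  expect_identical(as.character(candidateSeqs(det)),
                   as.character(candidateSeqs(det2)))
})

test_that("reads from a repeat-free genome assemble nothing long", {
  g <- Biostrings::DNAStringSet(c(c1 = oracle_rand_dna(60000, seed = 91)))
  reads <- simulateReads(g, read_len = 100L, depth = 20, seed = 92L)
  det <- detectFromReads(reads, k = 21L, abundance_factor = 5)
  expect_true(length(det) == 0 ||
                all(Biostrings::width(candidateSeqs(det)) < 500))
})

test_that("detection is strand-symmetric: a reverse-complemented genome yields mirrored spans", {
  w <- small_world()
  rcg <- Biostrings::reverseComplement(w$genome)
  names(rcg) <- names(w$genome)
  for (fun in list(detectLTRPairs, detectTIRMite, detectSINE)) {
    fwd <- fun(w$genome)
    rev <- fun(rcg)
    expect_equal(length(fwd), length(rev))
    if (length(fwd) > 0) {
      L <- Biostrings::width(w$genome)[1]
      fi <- candidateInfo(fwd); ri <- candidateInfo(rev)
      mirrored_start <- sort(L - fi$end + 1L)
      ## spans mirror up to the +/- TSD boundary jitter
      expect_true(all(abs(sort(ri$start) - mirrored_start) <= 3))
    }
  }
})
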