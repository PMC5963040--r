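test_that("LTR templates carry identical direct terminal repeats", {
  tm <- teTemplateCatalog()
  s <- makeTemplateSequence(tm$copia1, seed = 17)
  x <- as.character(s$seq)
  L <- nchar(x)
  expect_equal(L, 4200)
  expect_identical(substr(x, 1, 200), substr(x, L - 199, L))
})

test_that("TIR templates end in the reverse complement of their start", {
  tm <- teTemplateCatalog()
  s <- makeTemplateSequence(tm$mariner1, seed = 17)
  x <- as.character(s$seq)
  L <- nchar(x)
  expect_identical(substr(x, 1, 30), oracle_revcomp(substr(x, L - 29, L)))
})

test_that("MITE templates contain no ORF of 300 bp or more in any frame", {
  tm <- teTemplateCatalog()
  for (sd in c(17, 18, 19)) {
    x <- as.character(makeTemplateSequence(tm$mite1, seed = sd)$seq)
    expect_lt(oracle_max_orf_nt(x), 300)
  }
})

test_that("poly-A tailed templates end in their configured tail", {
  tm <- teTemplateCatalog()
  x <- as.character(makeTemplateSequence(tm$sine1, seed = 17)$seq)
  expect_identical(substr(x, nchar(x) - 11, nchar(x)), strrep("A", 12))
  y <- as.character(makeTemplateSequence(tm$line1, seed = 17)$seq)
  expect_identical(substr(y, nchar(y) - 15, nchar(y)), strrep("A", 16))
})

test_that("domain tokens are embedded in-frame inside the transposase ORF", {
  tm <- teTemplateCatalog()
  s <- makeTemplateSequence(tm$mariner1, seed = 17)
  orf_nt <- substr(as.character(s$seq), s$orf_range[1], s$orf_range[2])
  aa <- oracle_translate(orf_nt)   # independent codon-table translation
  expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  expect_true(grepl(domainPeptides()[["TASE"]], aa, fixed = TRUE))
  expect_true(grepl(s$var_aa, aa, fixed = TRUE))
})

test_that("a template too small for its structure raises a sizing error", {
  t <- teTemplate("tiny", "Copia", "LTR", "I", total_len = 450L, tsd_len = 5L,
                  ltr_len = 200L, orf_domains = c("RT", "INT"))
  expect_error(makeTemplateSequence(t, seed = 1), "too small")
})

test_that("template realization is deterministic in the seed", {
  tm <- teTemplateCatalog()
  a <- as.character(makeTemplateSequence(tm$copia1, seed = 5)$seq)
  b <- as.character(makeTemplateSequence(tm$copia1, seed = 5)$seq)
  c <- as.character(makeTemplateSequence(tm$copia1, seed = 6)$seq)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("zero-noise planted copies sit exactly at their truth intervals with TSD flanks", {
  w <- small_world()
  tr <- w$truth
  for (i in seq_along(tr)) {
    fam <- S4Vectors::mcols(tr)$family_id[i]
    tpl <- as.character(w$seqs[[fam]]$seq)
    ctg <- w$genome[[as.character(GenomicRanges::seqnames(tr))[i]]]
    ex <- as.character(Biostrings::subseq(ctg, GenomicRanges::start(tr)[i],
                                          GenomicRanges::end(tr)[i]))
    if (as.character(GenomicRanges::strand(tr))[i] == "-")
      ex <- oracle_revcomp(ex)
    expect_identical(ex, tpl)
    tsd <- S4Vectors::mcols(tr)$tsd[i]
    left <- as.character(Biostrings::subseq(
      ctg, GenomicRanges::start(tr)[i] - nchar(tsd),
      GenomicRanges::start(tr)[i] - 1))
    right <- as.character(Biostrings::subseq(
      ctg, GenomicRanges::end(tr)[i] + 1,
      GenomicRanges::end(tr)[i] + nchar(tsd)))
    expect_identical(left, tsd)
    expect_identical(right, tsd)
  }
})

test_that("per-copy divergence matches the requested rate", {
  tm <- teTemplateCatalog()
  sub <- tm["copia1"]
  pc <- plantCopies(120000L, sub, copies_per_family = 6L, divergence = 0.05,
                    seed = 99L)
  tpl <- as.character(templateSequences(sub, 99L)$copia1$seq)
  ids <- vapply(seq_along(pc$truth), function(i) {
    ex <- as.character(Biostrings::subseq(
      pc$genome[[as.character(GenomicRanges::seqnames(pc$truth))[i]]],
      GenomicRanges::start(pc$truth)[i], GenomicRanges::end(pc$truth)[i]))
    if (as.character(GenomicRanges::strand(pc$truth))[i] == "-")
      ex <- oracle_revcomp(ex)
    oracle_hamming_identity(ex, tpl)
  }, numeric(1))
  ## binomial sampling error for n=4200, p=0.05 is ~0.4% per copy
  expect_equal(mean(ids), 0.95, tolerance = 0.012)
})

test_that("planting zero copies returns pure background and empty truth", {
  pc <- plantCopies(50000L, teTemplateCatalog()["mite1"],
                    copies_per_family = 0L, seed = 3L)
  expect_equal(sum(Biostrings::width(pc$genome)), 50000)
  expect_equal(length(pc$truth), 0)
})

test_that("planting beyond capacity raises a capacity error", {
  expect_error(plantCopies(30000L, teTemplateCatalog()["gypsy1"],
                           copies_per_family = 10L, seed = 3L),
               "capacity")
})

test_that("fragmentation truncates to a prefix and records completeness", {
  tm <- teTemplateCatalog()["gypsy1"]
  pc <- plantCopies(200000L, tm, copies_per_family = 8L, divergence = 0,
                    frag_prob = 1, seed = 12L)
  comp <- S4Vectors::mcols(pc$truth)$completeness
  expect_true(all(comp < 1))
  expect_true(all(GenomicRanges::width(pc$truth) ==
                    pmax(50, floor(5200 * comp))))
})

test_that("simulated read count follows ceil(depth * total_bp / read_len)", {
  w <- small_world()
  reads <- simulateReads(w$genome, read_len = 100L, depth = 2, seed = 7L)
  expect_equal(length(reads), ceiling(2 * sum(Biostrings::width(w$genome)) / 100))
  expect_true(all(Biostrings::width(reads) == 100))
})

test_that("error-free reads are exact substrings of the genome or its reverse complement", {
  w <- small_world()
  reads <- simulateReads(w$genome, read_len = 80L, depth = 0.05, seed = 8L)
  g <- as.character(w$genome[[1]])
  grc <- oracle_revcomp(g)
  for (r in as.character(head(reads, 25)))
    expect_true(grepl(r, g, fixed = TRUE) || grepl(r, grc, fixed = TRUE))
})

test_that("read simulation is deterministic under a fixed seed", {
  w <- small_world()
  r1 <- simulateReads(w$genome, read_len = 100L, depth = 0.2, seed = 5L)
  r2 <- simulateReads(w$genome, read_len = 100L, depth = 0.2, seed = 5L)
  expect_identical(as.character(r1), as.character(r2))
  expect_error(simulateReads(w$genome, read_len = 10 * sum(Biostrings::width(w$genome)),
                             depth = 1, seed = 1L), "exceeds")
})

test_that("activity fixtures separate expressed from silent copies", {
  w <- small_world()
  act <- simulateActivity(w$truth, expressed_families = "mariner1",
                          peptide_source_families = "mariner1",
                          templates = w$templates, seed = 301L)
  cov <- act$coverage
  expect_true(all(cov$covered_fraction[cov$family_id == "mariner1"] >= 0.95))
  expect_true(all(cov$covered_fraction[cov$family_id != "mariner1"] < 0.9))
})

test_that("simulated peptides translate out of the source family's transposase ORF", {
  w <- small_world()
  act <- simulateActivity(w$truth, expressed_families = "mariner1",
                          peptide_source_families = "mariner1",
                          templates = w$templates, seed = 301L)
  s <- w$seqs$mariner1
  orf_nt <- substr(as.character(s$seq), s$orf_range[1], s$orf_range[2])
  aa <- oracle_translate(orf_nt)
  expect_gte(length(act$peptides), 1)
  expect_true(all(Biostrings::width(act$peptides) >= 8))
  expect_true(all(Biostrings::width(act$peptides) <= 25))
  for (p in as.character(act$peptides))
    expect_true(grepl(p, aa, fixed = TRUE))
  expect_error(simulateActivity(w$truth, "nosuchfam", character(0),
                                w$templates, seed = 1L), "not present")
})
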