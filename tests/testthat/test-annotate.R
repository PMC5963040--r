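mk_lib <- function(seqs, order = "LTR", superfamily = "Copia",
                   autonomy = "autonomous", name = "lib") {
  n <- length(seqs)
  TELibrary(name, seqs, S4Vectors::DataFrame(
    wicker_class = rep(if (order %in% c("TIR", "MITE", "Helitron")) "II" else "I", n),
    order = rep(order, n), superfamily = rep(superfamily, n),
    autonomy = rep(autonomy, n)))
}

test_that("library alignment chains fragments split by a short insertion", {
  tpl <- oracle_rand_dna(2000, seed = 401)
  g <- Biostrings::DNAStringSet(c(c1 = paste0(
    oracle_rand_dna(5000, seed = 402), substr(tpl, 1, 1000),
    oracle_rand_dna(200, seed = 403),   # insertion inside the copy
    substr(tpl, 1001, 2000), oracle_rand_dna(5000, seed = 404))))
  lib <- mk_lib(Biostrings::DNAStringSet(c(fam = tpl)))
  gr <- alignLibraryToGenome(lib, g, chain_gap = 500L)
  expect_equal(length(gr), 1)
  expect_gte(S4Vectors::mcols(gr)$library_coverage, 0.95)
  expect_equal(GenomicRanges::start(gr), 5001)
  expect_equal(GenomicRanges::end(gr), 7200)   # both fragments plus the insert
})

test_that("library entries absent from the genome produce no intervals", {
  g <- Biostrings::DNAStringSet(c(c1 = oracle_rand_dna(30000, seed = 405)))
  lib <- mk_lib(Biostrings::DNAStringSet(c(fam = oracle_rand_dna(1000, seed = 406))))
  expect_equal(length(alignLibraryToGenome(lib, g)), 0)
})

test_that("FLC selection keeps near-full-length entries and drops fragments", {
  lib <- mk_lib(Biostrings::DNAStringSet(c(good = strrep("ACGT", 250),
                                           chim = strrep("TTGA", 250))))
  gr <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(1, 5000), width = c(960, 600)),
    library_id = c("good", "chim"),
    pct_identity = c(0.99, 0.99), library_coverage = c(0.96, 0.60),
    score = c(1000, 500))
  flc <- selectFLC(gr, lib, flc_cov = 0.95)
  expect_identical(names(librarySeqs(flc)), "good")
  expect_equal(length(selectFLC(gr[integer(0)], lib)), 0)
})

test_that("overlap resolution lets the higher score win and trims the loser", {
  gr <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(1000, 1400, 5000), end = c(2000, 2600, 5500)),
    strand = "+",
    library_id = c("winner", "loser", "free"),
    pct_identity = 0.95, library_coverage = 0.9,
    score = c(900, 300, 100),
    order = "LTR", superfamily = "Copia", wicker_class = "I",
    autonomy = "autonomous")
  res <- TEforge:::.resolveOverlaps(gr, min_len = 80L)
  md <- S4Vectors::mcols(res)
  expect_equal(GenomicRanges::start(res[md$library_id == "loser"]), 2001)
  expect_equal(GenomicRanges::end(res[md$library_id == "loser"]), 2600)
  expect_equal(length(res), 3)
  ## remainder below 80 bp disappears
  gr2 <- gr
  IRanges::end(gr2)[2] <- 2050   # loser remainder = 50 bp
  res2 <- TEforge:::.resolveOverlaps(gr2, min_len = 80L)
  expect_false("loser" %in% S4Vectors::mcols(res2)$library_id)
  ## identical duplicates: exactly one survives
  dup <- c(gr[1], gr[1])
  expect_equal(length(TEforge:::.resolveOverlaps(dup)), 1)
  ## pairwise non-overlap property
  for (ct in unique(as.character(GenomicRanges::seqnames(res)))) {
    rr <- IRanges::IRanges(GenomicRanges::start(res), GenomicRanges::end(res))
    expect_equal(length(IRanges::findOverlaps(rr, rr)), length(rr))
  }
})

test_that("proportions use union semantics and half-up rounding", {
  g <- Biostrings::DNAStringSet(c(c1 = strrep("A", 100)))
  gr1 <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 20), order = "LTR")
  expect_equal(computeProportions(gr1, g)$pct, 20.00)
  gr2 <- GenomicRanges::GRanges(c("c1", "c1"),
                                IRanges::IRanges(c(1, 11), end = c(20, 30)),
                                order = c("LTR", "LTR"))
  expect_equal(computeProportions(gr2, g, "order")$pct, 30.00)
  expect_equal(computeProportions(GenomicRanges::GRanges(), g)$pct, 0)
})

test_that("union-length proportions agree with a per-base mask oracle", {
  set.seed(421)
  n <- 100000L
  g <- Biostrings::DNAStringSet(c(c1 = oracle_rand_dna(n, seed = 421)))
  starts <- sample(n - 2000L, 60)
  widths <- sample(100:2000, 60, replace = TRUE)
  ends <- pmin(starts + widths - 1L, n)
  cat_ <- sample(c("LTR", "TIR"), 60, replace = TRUE)
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(starts, ends), order = cat_)
  got <- computeProportions(gr, g, "order")
  for (cv in unique(cat_)) {
    bp <- oracle_union_length(starts[cat_ == cv], ends[cat_ == cv], n)
    expect_equal(got$bp[got$category == cv], bp)
    expect_equal(got$pct[got$category == cv], roundHalfUp(100 * bp / n, 2))
  }
})

test_that("the Russian-doll run reports nested, monotone proportions", {
  w <- small_world()
  det <- detectSimilarityNT(w$genome, w$databank, min_hit_len = 100L)
  red <- reduceRedundancy(det)
  routed <- routeDetections(red$kept)
  cls <- classifyCandidates(routed$to_classify, w$databank)
  libs <- buildNestedLibraries(routed$to_classify, cls)
  out <- runRussianDoll(libs, w$genome)
  rep <- out$report
  expect_lte(rep$autonomous_pct, rep$total_te_pct)
  expect_lte(rep$total_te_pct, rep$repeated_pct)
  expect_equal(rep$non_autonomous_pct,
               roundHalfUp(rep$total_te_pct - rep$autonomous_pct, 2))
  expect_equal(rep$uncategorized_repeat_pct,
               roundHalfUp(rep$repeated_pct - rep$total_te_pct, 2))
  ## no two surviving intervals of one annotation set overlap
  for (gr in out$annotations) {
    if (length(gr) < 2) next
    for (ct in unique(as.character(GenomicRanges::seqnames(gr)))) {
      sub <- gr[as.character(GenomicRanges::seqnames(gr)) == ct]
      rr <- IRanges::IRanges(GenomicRanges::start(sub), GenomicRanges::end(sub))
      expect_equal(length(IRanges::findOverlaps(rr, rr)), length(rr))
    }
  }
})

test_that("degenerate nesting (three equal libraries) reports equal proportions", {
  w <- small_world()
  tpl <- librarySeqs(w$databank)[1:3]
  cls <- libraryClassification(w$databank)[1:3, ]
  libs <- list(autonomous = TELibrary("autonomous", tpl, cls),
               total = TELibrary("total", tpl, cls),
               repeated = TELibrary("repeated", tpl, cls))
  out <- runRussianDoll(libs, w$genome)
  expect_equal(out$report$autonomous_pct, out$report$total_te_pct)
  expect_equal(out$report$total_te_pct, out$report$repeated_pct)
  expect_equal(out$report$non_autonomous_pct, 0)
  expect_equal(out$report$uncategorized_repeat_pct, 0)
})

test_that("nesting violations are rejected", {
  w <- small_world()
  libA <- mk_lib(Biostrings::DNAStringSet(c(a = oracle_rand_dna(500, seed = 431))))
  libB <- mk_lib(Biostrings::DNAStringSet(c(b = oracle_rand_dna(500, seed = 432))))
  expect_error(runRussianDoll(list(autonomous = libA, total = libB,
                                   repeated = libB), w$genome), "nesting")
})

test_that("cartography export writes BED rows and a per-contig summary", {
  g <- Biostrings::DNAStringSet(c(c1 = strrep("A", 10000), c2 = strrep("C", 10000)))
  gr <- GenomicRanges::GRanges(
    c("c1", "c1", "c2"), IRanges::IRanges(c(100, 4000, 200), width = 500),
    strand = "+", library_id = c("f1", "f2", "f1"),
    superfamily = c("Copia", "hAT", "Copia"))
  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  exportCartography(gr, g, bed, tsv)
  expect_equal(length(readLines(bed)), 3)
  tab <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 3)   # c1/Copia, c1/hAT, c2/Copia
  back <- readBed(bed)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
})
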