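# The rule cascade is tested twice: directly on hand-built evidence bundles
# (one per rule) and end-to-end on realized templates where the intended
# (class, order) is known by construction.

ev_stub <- function(length = 5000, terminal = "none", toks = character(0),
                    sim = NULL, orfs = 0, polyA = 0, tsd = NA_character_) {
  dh <- data.frame(token = toks, score = rep(200, length(toks)),
                   frame = rep(1L, length(toks)), start = rep(1L, length(toks)),
                   end = rep(300L, length(toks)), stringsAsFactors = FALSE)
  if (is.null(sim))
    sim <- data.frame(subject_id = character(0), subject_class = character(0),
                      subject_order = character(0),
                      subject_superfamily = character(0),
                      pct_identity = numeric(0), query_cov = numeric(0),
                      subject_cov = numeric(0), score = numeric(0))
  orfdf <- if (orfs > 0)
    data.frame(frame = 1L, start = 1L, end = 900L, aa = strrep("K", 300))
  else data.frame(frame = integer(0), start = integer(0), end = integer(0),
                  aa = character(0))
  list(length = length,
       terminal = list(repeat_kind = terminal, repeat_len = 100L,
                       repeat_identity = 0.95),
       orfs = orfdf, domain_hits = dh, similarity_hits = sim,
       polyA_len = polyA, tsd = tsd)
}

sim_row <- function(ord, sf, id = 0.95, scov = 0.9, score = 500) {
  data.frame(subject_id = paste0("x_", sf), subject_class = "I",
             subject_order = ord, subject_superfamily = sf,
             pct_identity = id, query_cov = 0.9, subject_cov = scov,
             score = score, stringsAsFactors = FALSE)
}

test_that("the autonomy rules fire in priority order", {
  ## (1) RT+INT+LTR similarity -> autonomous LTR
  r <- classifySequence(ev_stub(terminal = "direct_pair",
                                toks = c("RT", "INT"),
                                sim = sim_row("LTR", "Copia"), orfs = 1))
  expect_identical(r[c("wicker_class", "order", "superfamily", "autonomy")],
                   list(wicker_class = "I", order = "LTR",
                        superfamily = "Copia", autonomy = "autonomous"))
  ## (2) RT+LINE similarity -> autonomous LINE
  r <- classifySequence(ev_stub(toks = "RT", sim = sim_row("LINE", "L1"),
                                orfs = 1))
  expect_identical(r$order, "LINE")
  expect_identical(r$autonomy, "autonomous")
  ## (3) transposase domain alone -> autonomous TIR
  r <- classifySequence(ev_stub(toks = "TASE", orfs = 1))
  expect_identical(r$order, "TIR")
  expect_identical(r$wicker_class, "II")
  expect_identical(r$autonomy, "autonomous")
  ## (3b) TIR similarity without any ORF falls through to inheritance
  r <- classifySequence(ev_stub(sim = sim_row("TIR", "hAT"), orfs = 0))
  expect_identical(r$order, "TIR")
  expect_identical(r$autonomy, "non_autonomous")
})

test_that("non-coding structures classify as TRIM/LARD/MITE/SINE", {
  ## direct pair, no domains: TRIM below the 4 kb boundary, LARD above
  r <- classifySequence(ev_stub(length = 3000, terminal = "direct_pair"))
  expect_identical(r[c("order", "autonomy")],
                   list(order = "TRIM", autonomy = "non_autonomous"))
  r <- classifySequence(ev_stub(length = 4000, terminal = "direct_pair"))
  expect_identical(r$order, "TRIM")   # boundary itself is TRIM (<= 4 kb)
  r <- classifySequence(ev_stub(length = 6000, terminal = "direct_pair"))
  expect_identical(r$order, "LARD")
  ## inverted pair, no ORF, short -> MITE
  r <- classifySequence(ev_stub(length = 300, terminal = "inverted_pair"))
  expect_identical(r[c("wicker_class", "order", "autonomy")],
                   list(wicker_class = "II", order = "MITE",
                        autonomy = "non_autonomous"))
  ## poly-A + TSD + SINE-range length
  r <- classifySequence(ev_stub(length = 250, polyA = 12, tsd = "ACGTACGT"))
  expect_identical(r[c("order", "autonomy")],
                   list(order = "SINE", autonomy = "non_autonomous"))
})

test_that("similarity inheritance assigns the subject order at >=80/50", {
  r <- classifySequence(ev_stub(sim = sim_row("LTR", "Gypsy")))
  expect_identical(r$order, "LTR")
  expect_identical(r$superfamily, "Gypsy")
  expect_identical(r$autonomy, "non_autonomous")
  ## below 50% subject coverage no inheritance happens
  r <- classifySequence(ev_stub(sim = sim_row("LTR", "Gypsy", scov = 0.3)))
  expect_identical(r$order, "noCat")
})

test_that("empty evidence falls through to noCat/uncategorized", {
  r <- classifySequence(ev_stub())
  expect_identical(r[c("wicker_class", "order", "autonomy")],
                   list(wicker_class = "unknown", order = "noCat",
                        autonomy = "uncategorized"))
})

test_that("evidence extraction sees the planted structure of templates", {
  w <- small_world()
  cfg <- teConfig()
  ## Copia: direct terminal pair, RT and INT domains, LTR similarity
  ev <- extractEvidence(w$seqs$copia1$seq, w$databank, config = cfg)
  expect_identical(ev$terminal$repeat_kind, "direct_pair")
  expect_true(all(c("RT", "INT") %in% ev$domain_hits$token))
  expect_true("LTR" %in% ev$similarity_hits$subject_order)
  ## MITE: inverted pair, no ORFs, no domains
  ev <- extractEvidence(w$seqs$mite1$seq, w$databank, config = cfg)
  expect_identical(ev$terminal$repeat_kind, "inverted_pair")
  expect_equal(nrow(ev$orfs), 0)
  expect_equal(nrow(ev$domain_hits), 0)
  ## random sequence: no domain and no similarity evidence
  ev <- extractEvidence(oracle_rand_dna(2000, seed = 55), w$databank,
                        config = cfg)
  expect_equal(nrow(ev$domain_hits), 0)
  expect_equal(nrow(ev$similarity_hits), 0)
})

test_that("each zero-divergence template classifies to its intended class and order", {
  w <- small_world()
  cfg <- teConfig()
  for (fam in names(w$templates)) {
    tpl <- w$templates[[fam]]
    ev <- extractEvidence(w$seqs[[fam]]$seq, w$databank, config = cfg,
                          features = data.frame(repeat_kind = NA, tsd = "ACGTACGT",
                                                polyA_len = NA))
    got <- classifySequence(ev, cfg)
    expect_identical(got$order, tpl@order, label = fam)
    expect_identical(got$wicker_class, tpl@wicker_class, label = fam)
    expected_aut <- if (tpl@order %in% c("MITE", "SINE", "TRIM", "LARD"))
      "non_autonomous" else "autonomous"
    expect_identical(got$autonomy, expected_aut, label = fam)
  }
})

test_that("classification is invariant under reverse complement", {
  w <- small_world()
  cfg <- teConfig()
  for (fam in c("copia1", "mariner1", "mite1")) {
    fwd <- classifySequence(extractEvidence(w$seqs[[fam]]$seq, w$databank,
                                            config = cfg), cfg)
    rc <- classifySequence(extractEvidence(
      Biostrings::reverseComplement(w$seqs[[fam]]$seq), w$databank,
      config = cfg), cfg)
    expect_identical(fwd[c("wicker_class", "order", "autonomy")],
                     rc[c("wicker_class", "order", "autonomy")], label = fam)
  }
})

test_that("partitioning by autonomy is a disjoint cover", {
  cls <- S4Vectors::DataFrame(
    wicker_class = c("I", "II", "unknown", "I"),
    order = c("LTR", "TIR", "noCat", "SINE"),
    superfamily = c("Copia", "hAT", "unknown", "none"),
    autonomy = c("autonomous", "autonomous", "uncategorized", "non_autonomous"))
  p <- partitionByAutonomy(cls)
  expect_setequal(unlist(p), 1:4)
  expect_equal(lengths(p), c(autonomous = 2L, non_autonomous = 1L, noCat = 1L))
})
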