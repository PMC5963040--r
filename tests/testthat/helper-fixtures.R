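# Shared fixtures, built once per test run and memoized. The small world is
# used by most module tests; the full-scale planted benchmark is built by
# the acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_env, inherits = FALSE))
    assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# A compact planted world: 5 families, 150 kb, zero divergence.
small_world <- function() {
  memo_fixture("small_world", function() {
    tm <- teTemplateCatalog()
    sub <- tm[c("copia1", "mariner1", "hat1", "mite1", "sine1")]
    pc <- plantCopies(150000L, sub, copies_per_family = 2L, divergence = 0,
                      seed = 301L, n_contigs = 1L)
    list(templates = sub, seqs = templateSequences(sub, 301L),
         genome = pc$genome, truth = pc$truth,
         databank = referenceDatabank(sub, seed = 301L))
  })
}

# The full study conditions: 2 Mb background over 2 contigs, the complete
# 10-family catalogue, 5-20 copies per family, 2% divergence, 10%
# fragmentation, with reads and activity evidence. Built once and shared by
# the acceptance tests.
study_run <- function(seed = 42L) {
  memo_fixture(paste0("study_run_", seed), function() {
    tm <- teTemplateCatalog()
    ncop <- TEforge:::withSeed(seed, sample(5:20, length(tm), replace = TRUE))
    pc <- plantCopies(2000000L, tm, copies_per_family = ncop,
                      divergence = 0.02, frag_prob = 0.1, seed = seed,
                      n_contigs = 2L)
    db <- referenceDatabank(tm, seed = seed)
    reads <- simulateReads(pc$genome, read_len = 150L, depth = 4, seed = seed)
    act <- simulateActivity(pc$truth,
                            expressed_families = c("mariner1", "hat1", "copia1"),
                            peptide_source_families = c("mariner1", "hat1"),
                            templates = tm, seed = seed)
    res <- runPipeline(pc$genome, db, reads = reads, outdir = NULL,
                       reference = db, transcripts = act$transcripts,
                       peptides = act$peptides)
    list(templates = tm, planted = pc, databank = db, activity_in = act,
         result = res)
  })
}
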