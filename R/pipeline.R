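# End-to-end orchestration: detect -> curate -> classify -> families ->
# annotate (-> evaluate -> activity when the corresponding inputs are
# given), with every intermediate written to a run directory and a manifest
# recording configuration, seed and per-stage counts.

#' Run all four detection approaches
#'
#' @param genome named DNAStringSet
#' @param nt_library classified \linkS4class{TELibrary} databank
#' @param reads optional DNAStringSet of unassembled reads
#' @param domain_peptides named peptide vector
#' @param config a \linkS4class{TEConfig}
#' @return a combined \linkS4class{TECandidates}
#' @export
detectAll <- function(genome, nt_library, reads = NULL,
                      domain_peptides = domainPeptides(),
                      config = teConfig()) {
  parts <- list(
    detectSimilarityNT(genome, nt_library,
                       min_identity = config[["min_identity"]],
                       min_hit_len = config[["min_hit_len"]]),
    detectSimilarityProt(genome, domain_peptides,
                         min_score = config[["domain_min_score"]]),
    detectLTRPairs(genome, min_ltr = config[["ltr_min"]],
                   max_ltr = config[["ltr_max"]],
                   min_elem = config[["ltr_elem_min"]],
                   max_elem = config[["ltr_elem_max"]],
                   min_ltr_identity = config[["ltr_identity"]],
                   tsd_range = config[["ltr_tsd"]]),
    detectTIRMite(genome, min_tir = config[["tir_min"]],
                  max_elem = config[["mite_max_len"]],
                  tsd_range = config[["tir_tsd"]],
                  min_tir_identity = config[["tir_identity"]]),
    detectSINE(genome, len_range = config[["sine_len_range"]],
               min_tail = config[["sine_min_tail"]],
               tsd_range = config[["sine_tsd"]]),
    detectRepetitive(genome, k = config[["repeat_k"]],
                     min_copies = config[["repeat_min_copies"]]))
  if (!is.null(reads))
    parts[[length(parts) + 1L]] <- detectFromReads(
      reads, k = config[["reads_k"]],
      abundance_factor = config[["abundance_factor"]])
  parts <- Filter(function(p) length(p) > 0L, parts)
  if (length(parts) == 0L) return(emptyCandidates())
  out <- parts[[1]]
  if (length(parts) > 1L) out <- do.call(c, parts)
  ## re-key ids to be globally unique while keeping detector provenance
  seqs <- candidateSeqs(out)
  names(seqs) <- sprintf("%s", names(seqs))
  out
}

#' Run the whole pipeline
#'
#' Executes detection, curation, classification, family building, nested
#' annotation, and — when a truth/reference or activity evidence is given —
#' evaluation and activity crossing. All intermediates are written under
#' \code{outdir}; reruns with the same inputs and seed are byte-identical.
#'
#' @param genome named DNAStringSet (or FASTA path)
#' @param nt_library classified \linkS4class{TELibrary} databank
#' @param reads optional DNAStringSet (or FASTA path)
#' @param outdir run directory (created if missing); NULL to skip writing
#' @param config a \linkS4class{TEConfig}
#' @param domain_peptides named peptide vector
#' @param reference optional \linkS4class{TELibrary} for the detection
#'   benchmark
#' @param transcripts optional GRanges or coverage data.frame for the
#'   activity stage
#' @param peptides optional AAStringSet for the activity stage
#' @return list with elements detections, curated, classification,
#'   libraries, annotation (runRussianDoll output), benchmark (or NULL),
#'   activity (or NULL), manifest
#' @export
runPipeline <- function(genome, nt_library, reads = NULL, outdir = NULL,
                        config = teConfig(),
                        domain_peptides = domainPeptides(),
                        reference = NULL, transcripts = NULL,
                        peptides = NULL) {
  if (is.character(genome)) genome <- readFasta(genome)
  if (is.character(reads)) reads <- readFasta(reads)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  wr <- function(obj, fn, writer) if (!is.null(outdir)) writer(obj, file.path(outdir, fn))
  counts <- list()

  ## Step 1: detection + curation
  det <- detectAll(genome, nt_library, reads = reads,
                   domain_peptides = domain_peptides, config = config)
  counts$detected <- as.list(table(candidateInfo(det)$approach))
  filt <- filterMinLength(det, config[["min_detected_len"]])
  counts$after_length_filter <- length(filt)
  red <- reduceRedundancy(filt)
  counts$after_redundancy <- length(red$kept)
  wr(red$kept, "detections.fasta", function(o, p) writeFasta(candidateSeqs(o), p))
  if (!is.null(outdir))
    write.table(red$removed, file.path(outdir, "redundancy_removals.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  ## Step 2: routing + classification + families
  routed <- routeDetections(red$kept)
  cls <- classifyCandidates(routed$to_classify, nt_library,
                            domain_peptides = domain_peptides, config = config)
  counts$autonomy_bins <- lapply(partitionByAutonomy(cls), length)
  fams <- buildFamilies(routed$to_classify, cls, config = config)
  counts$n_families <- sum(vapply(fams, length, integer(1)))
  libs <- buildNestedLibraries(routed$to_classify, cls, families = fams,
                               direct_nonautonomous = routed$direct_nonautonomous,
                               direct_classification = routed$direct_classification)
  counts$library_sizes <- lapply(libs, length)
  if (!is.null(outdir)) {
    for (nm in names(libs)) {
      s <- librarySeqs(libs[[nm]])
      cl <- libraryClassification(libs[[nm]])
      lab <- paste0(vapply(seq_along(s), function(i)
        wickerCode(cl$order[i], cl$superfamily[i]), character(1)),
        "_", names(s))
      s2 <- s; names(s2) <- lab
      writeFasta(s2, file.path(outdir, paste0("library_", nm, ".fasta")))
    }
    write.table(as.data.frame(cls), file.path(outdir, "classification.tsv"),
                sep = "\t", quote = FALSE, row.names = TRUE, col.names = NA)
  }

  ## Step 3: Russian-doll annotation
  cache <- new.env(parent = emptyenv())
  anno <- runRussianDoll(libs, genome, config = config, cache = cache)
  counts$annotation_bp <- lapply(anno$annotations, function(gr)
    sum(width(reduce(granges(gr), ignore.strand = TRUE))))
  if (!is.null(outdir)) {
    for (nm in names(anno$annotations))
      writeAnnotationGFF3(anno$annotations[[nm]], genome,
                          file.path(outdir, paste0("annotation_", nm, ".gff3")))
    exportCartography(anno$annotations$autonomous, genome,
                      file.path(outdir, "cartography.bed"),
                      file.path(outdir, "cartography.tsv"))
    jsonlite::write_json(anno$report, file.path(outdir, "proportions.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  ## optional evaluation
  bench <- NULL
  if (!is.null(reference)) {
    bench <- list(records = benchmarkDetection(
      red$kept, reference, partial_cov = config[["partial_cov"]],
      complete_cov = config[["complete_cov"]]))
    bench$summary <- summarizeDetection(bench$records,
                                        partial_cov = config[["partial_cov"]],
                                        complete_cov = config[["complete_cov"]])
    bench$contribution <- approachContribution(bench$records)
    if (!is.null(outdir))
      write.table(bench$records, file.path(outdir, "benchmark.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## optional activity crossing
  act <- NULL
  if (!is.null(transcripts)) {
    copies <- anno$annotations$autonomous
    if (length(copies) > 0L) {
      mcols(copies)$family_id <- mcols(copies)$library_id
      mcols(copies)$copy_id <- sprintf("%s_copy%03d", mcols(copies)$library_id,
                                       ave(seq_along(copies),
                                           mcols(copies)$library_id,
                                           FUN = seq_along))
      expr <- transcriptCoverage(copies, transcripts,
                                 expressed_cov = config[["expressed_cov"]])
      reps <- librarySeqs(libs$autonomous)
      copseqs <- lapply(split(seq_along(copies), mcols(copies)$family_id),
                        function(ix) {
                          DNAStringSet(vapply(ix, function(i)
                            as.character(subseq(
                              genome[[as.character(seqnames(copies))[i]]],
                              start(copies)[i], end(copies)[i])),
                            character(1)))
                        })
      act <- flagPotentiallyActive(expr, reps,
                                   if (is.null(peptides)) AAStringSet() else peptides,
                                   copies_by_family = copseqs)
      if (!is.null(outdir))
        write.table(act, file.path(outdir, "activity.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- list(package = "TEforge",
                   version = as.character(utils::packageVersion("TEforge")),
                   seed = config[["seed"]],
                   config = config@params,
                   read_based_run = !is.null(reads),
                   counts = counts)
  if (!is.null(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(detections = det, curated = red$kept, routed = routed,
       classification = cls, families = fams, libraries = libs,
       annotation = anno, benchmark = bench, activity = act,
       manifest = manifest)
}
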