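# Similarity-based detection (approach 1): nucleotide search of a TE
# databank against the genome, and protein-domain search of the consensus
# peptide set against six-frame translations.

#' Nucleotide similarity detection against a TE databank
#'
#' Seed-and-extend local alignment of each library entry against both
#' strands of every contig. Hits at or above \code{min_identity} and
#' \code{min_hit_len} are emitted as plus-strand genome substrings with
#' their origin recorded.
#'
#' @param genome named DNAStringSet
#' @param library DNAStringSet (e.g. \code{librarySeqs(referenceDatabank())})
#'   or a \linkS4class{TELibrary}
#' @param min_identity minimum hit identity
#' @param min_hit_len minimum hit length (bp)
#' @return a \linkS4class{TECandidates} (approach "similarity")
#' @export
detectSimilarityNT <- function(genome, library, min_identity = 0.8,
                               min_hit_len = 100L) {
  if (is(library, "TELibrary")) library <- librarySeqs(library)
  out_seqs <- character(0); rows <- list()
  if (length(library) > 0 && length(genome) > 0) {
    for (li in seq_along(library)) {
      q <- as.character(library[[li]])
      for (ci in seq_along(genome)) {
        hits <- seedExtendHits(q, genome[[ci]], min_identity = min_identity,
                               min_len = min_hit_len)
        if (nrow(hits) == 0L) next
        for (h in seq_len(nrow(hits))) {
          out_seqs <- c(out_seqs, as.character(
            subseq(genome[[ci]], hits$s_start[h], hits$s_end[h])))
          rows[[length(rows) + 1L]] <- data.frame(
            contig = names(genome)[ci], start = hits$s_start[h],
            end = hits$s_end[h], strand = hits$strand[h],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out_seqs) == 0L) return(emptyCandidates())
  rd <- do.call(rbind, rows)
  seqs <- DNAStringSet(out_seqs)
  names(seqs) <- sprintf("simnt_%04d", seq_along(seqs))
  TECandidates(seqs, approach = "similarity", detector = "similarity_nt",
               contig = rd$contig, start = rd$start, end = rd$end,
               strand = rd$strand)
}

.blosumEnv <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosumEnv$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosumEnv$m <- e$BLOSUM62
  }
  .blosumEnv$m
}

# Ungapped-style local alignment score of a peptide against an amino-acid
# string (gaps priced out of reach).
.peptideAlign <- function(pep, aa) {
  pairwiseAlignment(AAString(pep), AAString(aa), type = "local",
                    substitutionMatrix = .blosum62(),
                    gapOpening = 1000, gapExtension = 1000)
}

#' Protein-domain similarity detection
#'
#' Stop-free runs of at least \code{orf_min_aa} residues are extracted from
#' all six reading frames of every contig; each domain consensus peptide is
#' aligned against them (BLOSUM62, ungapped). Regions scoring at or above
#' \code{min_score} are emitted with a symmetric flank, merged per strand.
#'
#' @param genome named DNAStringSet
#' @param domain_peptides named character vector (see
#'   \code{\link{domainPeptides}})
#' @param min_score minimum alignment score
#' @param orf_min_aa minimum stop-free run length scanned (residues)
#' @param flank flank added around a scoring region (bp)
#' @return a \linkS4class{TECandidates} (approach "similarity")
#' @export
detectSimilarityProt <- function(genome, domain_peptides = domainPeptides(),
                                 min_score = 100, orf_min_aa = 100L,
                                 flank = 2000L) {
  if (length(domain_peptides) == 0L) .stopf("empty domain peptide set")
  regions <- list()
  for (ci in seq_along(genome)) {
    L <- width(genome)[ci]
    for (fr in sixFrames(genome[[ci]])) {
      runs <- stopFreeRuns(fr$aa, orf_min_aa)
      if (nrow(runs) == 0L) next
      for (r in seq_len(nrow(runs))) {
        seg <- substr(fr$aa, runs$aa_start[r], runs$aa_end[r])
        for (tok in names(domain_peptides)) {
          pa <- .peptideAlign(domain_peptides[[tok]], seg)
          if (score(pa) < min_score) next
          a1 <- runs$aa_start[r] + start(subject(pa)) - 1L
          a2 <- runs$aa_start[r] + end(subject(pa)) - 1L
          nt <- aaRangeToNt(a1, a2, fr$frame, L)
          regions[[length(regions) + 1L]] <- data.frame(
            contig = names(genome)[ci],
            start = max(1L, nt[1] - flank), end = min(L, nt[2] + flank),
            strand = if (fr$frame > 0) "+" else "-",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(regions) == 0L) return(emptyCandidates())
  rd <- do.call(rbind, regions)
  ## merge overlapping emitted regions per contig and strand
  gr <- GRanges(rd$contig, IRanges(rd$start, rd$end), strand = rd$strand)
  gr <- reduce(gr)
  out_seqs <- vapply(seq_along(gr), function(i)
    as.character(subseq(genome[[as.character(seqnames(gr))[i]]],
                        start(gr)[i], end(gr)[i])), character(1))
  seqs <- DNAStringSet(out_seqs)
  names(seqs) <- sprintf("simprot_%04d", seq_along(seqs))
  TECandidates(seqs, approach = "similarity", detector = "domain_prot",
               contig = as.character(seqnames(gr)), start = start(gr),
               end = end(gr), strand = as.character(strand(gr)))
}
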