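# Family building under the 80-80-80 rule (>=80% identity over >=80% of the
# shorter sequence, alignment >=80 bp) with Markov-style graph clustering,
# and assembly of the three nested "Russian doll" libraries.

#' Build the similarity graph over same-superfamily sequences
#'
#' An edge joins two sequences iff their best local alignments reach
#' \code{min_identity} over at least \code{min_cov} of the shorter
#' sequence's length with an alignment of at least \code{min_len} bp; the
#' edge weight is identity times coverage.
#'
#' @param seqs named DNAStringSet (one putative superfamily)
#' @param min_identity,min_cov,min_len the 80-80-80 thresholds
#' @return data.frame(a, b, weight)
#' @export
buildSimilarityGraph <- function(seqs, min_identity = 0.8, min_cov = 0.8,
                                 min_len = 80L) {
  n <- length(seqs)
  ids <- names(seqs)
  edges <- list()
  if (n >= 2L) {
    ch <- as.character(seqs)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (sharedKmerFrac(ch[i], ch[j], k = 12L) == 0) next
        hits <- pairHits(ch[i], ch[j], min_identity = min_identity,
                         min_len = min_len)
        if (nrow(hits) == 0L) next
        cov <- .coverageOfShorter(hits, nchar(ch[i]), nchar(ch[j]))
        if (cov < min_cov) next
        idw <- sum(hits$identity * (hits$s_end - hits$s_start + 1L)) /
          sum(hits$s_end - hits$s_start + 1L)
        edges[[length(edges) + 1L]] <- data.frame(
          a = ids[i], b = ids[j], weight = idw * min(cov, 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(edges) == 0L)
    return(data.frame(a = character(0), b = character(0), weight = numeric(0)))
  do.call(rbind, edges)
}

# Markov clustering: alternating expansion (matrix square) and inflation
# (entrywise power, column renormalization) on the column-stochastic weight
# matrix with self-loops, until the matrix stops changing.
.mclClusters <- function(ids, edges, inflation = 1.5, tol = 1e-6,
                         max_iter = 100L) {
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(edges) > 0L) {
    ai <- match(edges$a, ids); bi <- match(edges$b, ids)
    M[cbind(ai, bi)] <- edges$weight
    M[cbind(bi, ai)] <- edges$weight
  }
  diag(M) <- pmax(apply(M, 2, max), 1e-3)
  norm <- function(m) sweep(m, 2, pmax(colSums(m), .Machine$double.eps), "/")
  M <- norm(M)
  for (it in seq_len(max_iter)) {
    M2 <- norm(norm(M %*% M)^inflation)
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  ## attractor interpretation: vertex j joins the cluster of every row i
  ## with non-negligible mass in column j; union-find over those links
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union_ <- function(x, y) { rx <- find(x); ry <- find(y); if (rx != ry) parent[max(rx, ry)] <<- min(rx, ry) }
  for (j in seq_len(n)) {
    for (i in which(M[, j] > 1e-3)) union_(i, j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(ids, roots)
}

#' Cluster same-superfamily sequences into 80-80-80 families
#'
#' Deterministic expansion/inflation iterations on the similarity graph
#' (inflation as given, convergence at max-change < 1e-6 or 100 rounds);
#' singletons become singleton families. A post-filter splits out any member
#' that violates the 80-80-80 rule against its cluster's longest member.
#'
#' @param seqs named DNAStringSet (one putative superfamily)
#' @param edges data.frame from \code{\link{buildSimilarityGraph}}
#' @param inflation MCL inflation parameter
#' @param min_identity,min_cov,min_len 80-80-80 thresholds for the post-filter
#' @return list of families; each family is a list(member_ids,
#'   representative_id)
#' @export
clusterFamilies <- function(seqs, edges, inflation = 1.5, min_identity = 0.8,
                            min_cov = 0.8, min_len = 80L) {
  ids <- names(seqs)
  if (length(ids) == 0L) return(list())
  clusters <- .mclClusters(ids, edges, inflation = inflation)
  fams <- list()
  for (cl in clusters) {
    cl <- sort(cl)
    if (length(cl) > 1L) {
      rep_id <- selectRepresentative(seqs[cl])
      keep <- cl[cl == rep_id]
      for (m in setdiff(cl, rep_id)) {
        hits <- pairHits(as.character(seqs[[m]]), as.character(seqs[[rep_id]]),
                         min_identity = min_identity, min_len = min_len)
        cov <- .coverageOfShorter(hits, width(seqs[m]), width(seqs[rep_id]))
        if (nrow(hits) > 0L && cov >= min_cov) keep <- c(keep, m)
        else fams[[length(fams) + 1L]] <- list(member_ids = m,
                                               representative_id = m)
      }
      fams[[length(fams) + 1L]] <- list(member_ids = sort(keep),
                                        representative_id = rep_id)
    } else {
      fams[[length(fams) + 1L]] <- list(member_ids = cl,
                                        representative_id = cl)
    }
  }
  ## deterministic family order and ids
  o <- order(vapply(fams, `[[`, character(1), "representative_id"))
  fams[o]
}

#' Select the representative of a family: longest member, ties by id
#' @param seqs named DNAStringSet of family members
#' @return the representative id
#' @export
selectRepresentative <- function(seqs) {
  stopifnot(length(seqs) > 0L)
  names(seqs)[order(-width(seqs), names(seqs))[1]]
}

#' Assemble the three nested Russian-doll libraries
#'
#' The autonomous library holds the family representatives of autonomous
#' families. The total library adds the non-autonomous entries — SINE, MITE
#' and TRIM from any source, LARD only when detected by the
#' repetitiveness-based approach — plus the MITE/SINE detector output routed
#' directly. The repeated library adds uncategorized (noCat) sequences
#' restricted to the repetitiveness-based approach.
#'
#' @param candidates classified \linkS4class{TECandidates} (the to_classify
#'   route)
#' @param classification DataFrame from \code{\link{classifyCandidates}}
#' @param families named list: for each autonomous (order, superfamily)
#'   group, the output of \code{\link{clusterFamilies}} — or NULL to treat
#'   every autonomous candidate as its own family
#' @param direct_nonautonomous TECandidates routed by
#'   \code{\link{routeDetections}}
#' @param direct_classification their preset classification DataFrame
#' @return list(autonomous, total, repeated) of \linkS4class{TELibrary}
#' @export
buildNestedLibraries <- function(candidates, classification, families = NULL,
                                 direct_nonautonomous = NULL,
                                 direct_classification = NULL) {
  seqs <- candidateSeqs(candidates)
  info <- candidateInfo(candidates)
  ids <- names(seqs)
  stopifnot(identical(rownames(classification), ids))
  direct_ids <- if (!is.null(direct_nonautonomous))
    names(candidateSeqs(direct_nonautonomous)) else character(0)
  if (length(intersect(ids, direct_ids)))
    .stopf("duplicate id across classified and direct inputs: %s",
           intersect(ids, direct_ids)[1])
  aut_idx <- which(classification$autonomy == "autonomous")
  ## family representatives (default: every autonomous candidate)
  rep_ids <- if (is.null(families)) ids[aut_idx]
    else unlist(lapply(families, function(fs)
      vapply(fs, `[[`, character(1), "representative_id")), use.names = FALSE)
  rep_ids <- sort(intersect(rep_ids, ids[aut_idx]))
  pick <- function(idx) {
    DataFrame(wicker_class = classification$wicker_class[idx],
              order = classification$order[idx],
              superfamily = classification$superfamily[idx],
              autonomy = classification$autonomy[idx])
  }
  aut_lib_idx <- match(rep_ids, ids)
  autonomous <- TELibrary("autonomous", seqs[aut_lib_idx], pick(aut_lib_idx))
  ## non-autonomous entries
  na_idx <- which(classification$autonomy == "non_autonomous")
  keep_na <- vapply(na_idx, function(i) {
    if (classification$order[i] == "LARD")
      info$approach[i] == "repetitiveness"
    else TRUE
  }, logical(1))
  na_idx <- na_idx[keep_na]
  total_seqs <- c(seqs[aut_lib_idx], seqs[na_idx])
  total_cls <- rbind(pick(aut_lib_idx), pick(na_idx))
  if (length(direct_ids)) {
    total_seqs <- c(total_seqs, candidateSeqs(direct_nonautonomous))
    total_cls <- rbind(total_cls, direct_classification[, colnames(total_cls)])
  }
  total <- TELibrary("total", total_seqs, total_cls)
  ## uncategorized repeats: noCat restricted to the repetitiveness approach
  nc_idx <- which(classification$autonomy == "uncategorized" &
                    info$approach == "repetitiveness")
  rep_seqs <- c(total_seqs, seqs[nc_idx])
  nc_cls <- DataFrame(wicker_class = rep("unknown", length(nc_idx)),
                      order = rep("noCat", length(nc_idx)),
                      superfamily = rep("unknown", length(nc_idx)),
                      autonomy = rep("uncategorized", length(nc_idx)))
  repeated <- TELibrary("repeated", rep_seqs, rbind(total_cls, nc_cls))
  ## nesting invariant
  stopifnot(all(names(librarySeqs(autonomous)) %in% names(librarySeqs(total))),
            all(names(librarySeqs(total)) %in% names(librarySeqs(repeated))))
  list(autonomous = autonomous, total = total, repeated = repeated)
}

#' Group autonomous candidates by (order, superfamily) and cluster each group
#'
#' Convenience wrapper producing the \code{families} argument of
#' \code{\link{buildNestedLibraries}}.
#'
#' @param candidates classified TECandidates
#' @param classification their classification DataFrame
#' @param config a \linkS4class{TEConfig}
#' @return named list of \code{\link{clusterFamilies}} outputs
#' @export
buildFamilies <- function(candidates, classification, config = teConfig()) {
  seqs <- candidateSeqs(candidates)
  aut <- which(classification$autonomy == "autonomous")
  if (length(aut) == 0L) return(list())
  key <- paste(classification$order[aut], classification$superfamily[aut],
               sep = "/")
  out <- list()
  for (grp in sort(unique(key))) {
    idx <- aut[key == grp]
    gseqs <- seqs[idx]
    edges <- buildSimilarityGraph(gseqs,
                                  min_identity = config[["family_identity"]],
                                  min_cov = config[["family_coverage"]],
                                  min_len = config[["family_min_len"]])
    out[[grp]] <- clusterFamilies(gseqs, edges,
                                  inflation = config[["mcl_inflation"]],
                                  min_identity = config[["family_identity"]],
                                  min_cov = config[["family_coverage"]],
                                  min_len = config[["family_min_len"]])
  }
  out
}
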