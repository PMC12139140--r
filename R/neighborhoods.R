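#' Build the expression neighborhood of a center gene
#'
#' Genes are visited in [closestGenes()] order (center first, then
#' descending correlation to the center, correlation ties by ascending gene
#' id). Each visited gene contributes all of its assigned variants until
#' the running total reaches \code{M}; when a gene's variants would
#' overshoot \code{M}, they are added in ascending (chrom, pos) order until
#' exactly \code{M} and the neighborhood is flagged truncated. Genes with
#' no assigned variants consume their rank position but contribute nothing.
#' If fewer than \code{M} variants exist in total the neighborhood is
#' flagged undersized.
#'
#' @param center center gene id (must be in the matrix).
#' @param corr a \linkS4class{CorrelationMatrix}.
#' @param variants prepared variant data.frame with \code{variant_id},
#'   \code{chrom}, \code{pos}, \code{gene_id}.
#' @param M neighborhood size (default 1000).
#' @return a \linkS4class{Neighborhood}.
#' @export
buildNeighborhood <- function(center, corr, variants, M = 1000L) {
  M <- as.integer(M)
  order <- closestGenes(corr, center)
  assigned <- !is.na(variants$gene_id)
  v <- variants[assigned, , drop = FALSE]
  byGene <- split(seq_len(nrow(v)), v$gene_id)
  ids <- character(0)
  used <- character(0)
  truncated <- FALSE
  for (g in order) {
    rows <- byGene[[g]]
    if (is.null(rows)) next
    rows <- rows[order(v$chrom[rows], v$pos[rows])]
    need <- M - length(ids)
    if (length(rows) > need) {
      rows <- rows[seq_len(need)]
      truncated <- TRUE
    }
    ids <- c(ids, v$variant_id[rows])
    used <- c(used, g)
    if (length(ids) >= M) break
  }
  methods::new("Neighborhood",
               centerGene = center, variantIds = ids, genesUsed = used,
               M = M, truncated = truncated,
               undersized = length(ids) < M)
}

#' Distance between two neighborhoods
#'
#' The Manhattan distance between the binary variant-membership encodings
#' of two neighborhoods built with the same M, which equals \code{M} minus
#' the number of shared variants. Symmetric; 0 iff the two full-size
#' variant sets are identical.
#'
#' @param a,b \linkS4class{Neighborhood} objects built with the same M.
#' @return integer distance in [0, M].
#' @export
neighborhoodDistance <- function(a, b) {
  if (neighborhoodSize(a) != neighborhoodSize(b))
    stop("neighborhoods built with different M")
  neighborhoodSize(a) - length(intersect(variantIds(a), variantIds(b)))
}

#' Density clustering of neighborhoods
#'
#' DBSCAN with minimum cluster size 1 over the [neighborhoodDistance()]
#' metric: with every point a core point, clusters are exactly the
#' connected components of the graph joining neighborhoods at distance
#' strictly less than \code{eps}. Chaining can break the complete-linkage
#' property (all within-cluster pairwise distances < eps); it is asserted
#' after clustering and any violating pairs are reported in a warning
#' rather than silently accepted.
#'
#' @param neighborhoods list of \linkS4class{Neighborhood} objects.
#' @param eps radius; default half the neighborhood size.
#' @return list with \code{membership} (integer cluster id per
#'   neighborhood), \code{clusters} (list of index vectors) and
#'   \code{complete_linkage} (logical).
#' @export
clusterNeighborhoods <- function(neighborhoods,
                                 eps = neighborhoodSize(neighborhoods[[1L]]) / 2) {
  n <- length(neighborhoods)
  if (n == 0L) stop("no neighborhoods to cluster")
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i)
    d[i, j] <- d[j, i] <- neighborhoodDistance(neighborhoods[[i]],
                                               neighborhoods[[j]])
  adj <- d < eps
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  complete <- TRUE
  bad <- character(0)
  for (cl in unique(memb)) {
    idx <- which(memb == cl)
    if (length(idx) < 2L) next
    pairs <- which(d[idx, idx, drop = FALSE] >= eps, arr.ind = TRUE)
    pairs <- pairs[pairs[, 1L] < pairs[, 2L], , drop = FALSE]
    if (nrow(pairs)) {
      complete <- FALSE
      bad <- c(bad, paste0(idx[pairs[, 1L]], "-", idx[pairs[, 2L]]))
    }
  }
  if (!complete)
    warning("chaining broke the complete-linkage property for pair(s): ",
            paste(bad, collapse = ", "))
  list(membership = as.integer(memb),
       clusters = split(seq_len(n), memb),
       complete_linkage = complete)
}
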