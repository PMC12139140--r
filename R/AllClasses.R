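#' @import methods
NULL

#' Gene-gene expression correlation matrix
#'
#' Holds a square, symmetric matrix of gene-gene expression correlations
#' (Geneshot-style), the backbone used to order "closest genes" when
#' building expression neighborhoods. Validity enforces symmetry (within
#' 1e-8), values in [-1, 1] (within 1e-8, guarding corrupt downloads),
#' matching dimnames, and that every diagonal entry is the maximum of its
#' row (a gene is at least as correlated with itself as with any other).
#'
#' @slot correlations numeric matrix with identical row/column gene ids.
#'
#' @seealso [readCorrelationMatrix()], [closestGenes()], [buildNeighborhood()]
#' @export
setClass("CorrelationMatrix",
  representation(correlations = "matrix"),
  validity = function(object) {
    m <- object@correlations
    msg <- character()
    if (!is.numeric(m)) msg <- c(msg, "correlations must be numeric")
    if (nrow(m) != ncol(m)) msg <- c(msg, "correlation matrix must be square")
    ids <- rownames(m)
    if (is.null(ids) || is.null(colnames(m)) || !identical(ids, colnames(m)))
      msg <- c(msg, "row and column gene ids must be present and identical")
    if (!is.null(ids) && anyDuplicated(ids))
      msg <- c(msg, "gene ids must be unique")
    if (is.numeric(m) && nrow(m) == ncol(m)) {
      if (max(abs(m - t(m))) > 1e-8)
        msg <- c(msg, "matrix is asymmetric beyond tolerance 1e-8")
      if (max(abs(m)) > 1 + 1e-8)
        msg <- c(msg, "correlations outside [-1, 1] beyond tolerance 1e-8")
      if (nrow(m) > 0 && any(diag(m) < apply(m, 1L, max) - 1e-8))
        msg <- c(msg, "diagonal entries must be the maximum of each row")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Expression neighborhood of a center gene
#'
#' The top-M variant set surrounding a center gene: genes are visited in
#' order of decreasing expression correlation to the center (center first)
#' and each visited gene contributes its assigned variants until the
#' running total reaches M.
#'
#' @slot centerGene center gene id.
#' @slot variantIds ordered, unique variant ids (length <= M).
#' @slot genesUsed genes that contributed at least the rank position, in
#'   visiting order.
#' @slot M requested neighborhood size.
#' @slot truncated TRUE when the last contributing gene was only partially
#'   included to hit M exactly.
#' @slot undersized TRUE when fewer than M variants were available in total.
#'
#' @seealso [buildNeighborhood()], [neighborhoodDistance()]
#' @export
setClass("Neighborhood",
  representation(
    centerGene = "character",
    variantIds = "character",
    genesUsed  = "character",
    M          = "integer",
    truncated  = "logical",
    undersized = "logical"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@centerGene) != 1L) msg <- c(msg, "centerGene must be a single id")
    if (anyDuplicated(object@variantIds)) msg <- c(msg, "variantIds must be unique")
    if (length(object@M) != 1L || is.na(object@M) || object@M < 1L)
      msg <- c(msg, "M must be a positive integer")
    if (length(object@variantIds) > object@M)
      msg <- c(msg, "neighborhood holds more than M variants")
    if (length(object@variantIds) < object@M && !object@undersized)
      msg <- c(msg, "fewer than M variants but undersized flag not set")
    if (length(msg)) msg else TRUE
  }
)

#' Multinomial Naive Bayes k-mer model
#'
#' Two-class multinomial Naive Bayes over 4^k k-mer count features with
#' uniform class priors and Laplace smoothing. Per class, the exponentiated
#' log word-probabilities sum to one.
#'
#' @slot k k-mer length.
#' @slot logTheta numeric matrix (2 x 4^k) of smoothed log word
#'   probabilities; rownames are the class labels (positive class first).
#' @slot classes class labels, positive first.
#' @slot alpha Laplace smoothing pseudo-count used at training.
#'
#' @seealso [nbTrain()], [nbScore()]
#' @export
setClass("NaiveBayesModel",
  representation(
    k        = "integer",
    logTheta = "matrix",
    classes  = "character",
    alpha    = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@classes) != 2L) msg <- c(msg, "exactly two classes required")
    if (nrow(object@logTheta) != 2L) msg <- c(msg, "logTheta must have two rows")
    if (ncol(object@logTheta) != 4L^object@k)
      msg <- c(msg, "logTheta must have 4^k columns")
    sums <- rowSums(exp(object@logTheta))
    if (any(abs(sums - 1) > 1e-9))
      msg <- c(msg, "per-class probabilities must sum to 1 within 1e-9")
    if (object@alpha <= 0) msg <- c(msg, "alpha must be positive")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "CorrelationMatrix", function(object) {
  cat("CorrelationMatrix with", nrow(object@correlations), "genes\n")
  ids <- rownames(object@correlations)
  if (length(ids))
    cat("  genes:", paste(utils::head(ids, 5L), collapse = ", "),
        if (length(ids) > 5L) "..." else "", "\n")
})

setMethod("show", "Neighborhood", function(object) {
  cat("Neighborhood centered on", object@centerGene,
      sprintf("(%d/%d variants, %d genes%s%s)\n",
              length(object@variantIds), object@M, length(object@genesUsed),
              if (object@truncated) ", truncated" else "",
              if (object@undersized) ", undersized" else ""))
})

setMethod("show", "NaiveBayesModel", function(object) {
  cat(sprintf("NaiveBayesModel: k = %d (%d features), classes %s vs %s, alpha = %g\n",
              object@k, ncol(object@logTheta),
              object@classes[1L], object@classes[2L], object@alpha))
})
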