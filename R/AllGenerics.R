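#' @include AllClasses.R
NULL

#' Accessors for the package's S4 classes
#'
#' @param x a \linkS4class{CorrelationMatrix}, \linkS4class{Neighborhood}
#'   or \linkS4class{NaiveBayesModel}.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("centerGene", function(x) standardGeneric("centerGene"))

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname accessors
#' @export
setGeneric("genesUsed", function(x) standardGeneric("genesUsed"))

#' @rdname accessors
#' @export
setGeneric("neighborhoodSize", function(x) standardGeneric("neighborhoodSize"))

#' @rdname accessors
#' @export
setGeneric("isTruncated", function(x) standardGeneric("isTruncated"))

#' @rdname accessors
#' @export
setGeneric("isUndersized", function(x) standardGeneric("isUndersized"))

#' @rdname accessors
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))

#' @rdname accessors
#' @export
setGeneric("classLogProbs", function(x) standardGeneric("classLogProbs"))

#' @rdname accessors
#' @export
setMethod("geneIds", "CorrelationMatrix", function(x) rownames(x@correlations))

#' @rdname accessors
#' @export
setMethod("centerGene", "Neighborhood", function(x) x@centerGene)

#' @rdname accessors
#' @export
setMethod("variantIds", "Neighborhood", function(x) x@variantIds)

#' @rdname accessors
#' @export
setMethod("genesUsed", "Neighborhood", function(x) x@genesUsed)

#' @rdname accessors
#' @export
setMethod("neighborhoodSize", "Neighborhood", function(x) x@M)

#' @rdname accessors
#' @export
setMethod("isTruncated", "Neighborhood", function(x) x@truncated)

#' @rdname accessors
#' @export
setMethod("isUndersized", "Neighborhood", function(x) x@undersized)

#' @rdname accessors
#' @export
setMethod("kmerLength", "NaiveBayesModel", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("classLogProbs", "NaiveBayesModel", function(x) x@logTheta)

#' Correlation lookup
#'
#' @param x a \linkS4class{CorrelationMatrix}.
#' @param gene1,gene2 gene ids.
#' @return the correlation between the two genes.
#' @export
setGeneric("correlation", function(x, gene1, gene2) standardGeneric("correlation"))

#' @rdname correlation
#' @export
setMethod("correlation", "CorrelationMatrix", function(x, gene1, gene2) {
  ids <- rownames(x@correlations)
  if (!gene1 %in% ids || !gene2 %in% ids)
    stop("gene id not present in correlation matrix")
  x@correlations[gene1, gene2]
})
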