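#' Spot spatial coordinates
#'
#' @param x a [SpatialTissue-class].
#' @return numeric matrix with one row per spot and columns `sdimx`, `sdimy`.
#' @export
setGeneric("spatialCoords", function(x) standardGeneric("spatialCoords"))

#' @rdname spatialCoords
#' @export
setMethod("spatialCoords", "SpatialTissue", function(x) {
  cd <- SummarizedExperiment::colData(x)
  m <- cbind(sdimx = cd$sdimx, sdimy = cd$sdimy)
  rownames(m) <- colnames(x)
  m
})

#' Ground-truth domain labels, if present
#'
#' @param x a [SpatialTissue-class].
#' @return integer vector of labels (one per spot) or `NULL`.
#' @export
setGeneric("domainTruth", function(x) standardGeneric("domainTruth"))

#' @rdname domainTruth
#' @export
setMethod("domainTruth", "SpatialTissue", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("domain" %in% colnames(cd)) as.integer(cd$domain) else NULL
})

#' Has the expression matrix been normalized?
#'
#' @param x a [SpatialTissue-class].
#' @return logical flag.
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname isNormalized
#' @export
setMethod("isNormalized", "SpatialTissue", function(x) {
  isTRUE(S4Vectors::metadata(x)$is_normalized)
})

#' Spot-by-gene expression matrix
#'
#' Returns expression in the orientation the embedding algebra uses
#' (spots as rows, genes as columns), i.e. the transpose of the stored assay.
#'
#' @param x a [SpatialTissue-class].
#' @param assay assay name; defaults to the first assay.
#' @return a spots-by-genes [Matrix::Matrix] (sparse when stored sparse).
#' @export
setGeneric("spotExpression", function(x, assay = NULL) standardGeneric("spotExpression"))

#' @rdname spotExpression
#' @export
setMethod("spotExpression", "SpatialTissue", function(x, assay = NULL) {
  if (is.null(assay)) assay <- SummarizedExperiment::assayNames(x)[1L]
  Matrix::t(SummarizedExperiment::assay(x, assay))
})

#' Embedding vector width of a gene-embedding table
#'
#' @param x a [GeneEmbeddingTable-class].
#' @return integer vector width.
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' @rdname embeddingDim
#' @export
setMethod("embeddingDim", "GeneEmbeddingTable", function(x) ncol(x@embeddings))

#' Gene symbols of an object
#'
#' @param x a [SpatialTissue-class] or [GeneEmbeddingTable-class].
#' @return character vector of symbols as supplied (original casing).
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname geneSymbols
#' @export
setMethod("geneSymbols", "SpatialTissue", function(x) rownames(x))

#' @rdname geneSymbols
#' @export
setMethod("geneSymbols", "GeneEmbeddingTable", function(x) rownames(x@embeddings))

#' Embedding matrix of a gene-embedding table
#'
#' @param x a [GeneEmbeddingTable-class].
#' @return numeric matrix, genes in rows.
#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))

#' @rdname embeddingMatrix
#' @export
setMethod("embeddingMatrix", "GeneEmbeddingTable", function(x) x@embeddings)

#' Mask a fraction of non-zero expression entries
#'
#' Simulates data-quality degradation: exactly `floor(fraction * nnz)`
#' entries, chosen uniformly without replacement among the non-zero entries,
#' are set to zero. All other entries are untouched, so the support of the
#' result is always a subset of the input's support.
#'
#' @param x a matrix, sparse [Matrix::Matrix], or [SpatialTissue-class].
#' @param fraction fraction of non-zero entries to zero, in `[0, 1]`.
#' @param seed integer seed; the same `(x, fraction, seed)` always yields the
#'   same mask.
#' @return An object of the same class as `x` with entries zeroed.
#' @export
#' @examples
#' m <- matrix(c(1, 0, 2, 3, 0, 4, 5, 6), nrow = 2)
#' sum(maskExpression(m, 0.5, seed = 1) != 0)  # 3 of 6 non-zeros survive
setGeneric("maskExpression", function(x, fraction, seed) standardGeneric("maskExpression"))

#' Fraction of non-zero entries
#'
#' @param x a matrix, sparse [Matrix::Matrix], or [SpatialTissue-class].
#' @return `nnz(x) / (nrow * ncol)` as a fraction (multiply by 100 for the
#'   percentage convention used in data-set summaries).
#' @export
setGeneric("expressionDensity", function(x) standardGeneric("expressionDensity"))
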