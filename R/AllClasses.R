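#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importClassesFrom Matrix Matrix
NULL

#' SpatialTissue: expression, coordinates and optional domain annotations
#'
#' `SpatialTissue` extends [SingleCellExperiment::SingleCellExperiment] with
#' the conventions this package relies on: genes are rows, spots are columns,
#' planar spot coordinates live in `colData` columns `sdimx`/`sdimy`, and an
#' optional ground-truth domain annotation lives in `colData$domain`.
#' Standard subsetting therefore keeps expression, coordinates and labels in
#' register automatically.
#'
#' Validity requires: no negative expression entries, finite coordinates with
#' one row per spot, gene symbols unique after case-folding, and (when
#' present) integer-like domain labels.
#'
#' @slot int_colData,int_elementMetadata,int_metadata inherited internals.
#' @seealso [SpatialTissue()] for construction, [spatialCoords()],
#'   [domainTruth()], [isNormalized()].
#' @export
setClass("SpatialTissue", contains = "SingleCellExperiment")

setValidity("SpatialTissue", function(object) {
  msgs <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sdimx", "sdimy") %in% colnames(cd))) {
    return("colData must contain spot coordinates 'sdimx' and 'sdimy'")
  }
  xy <- cbind(cd$sdimx, cd$sdimy)
  if (!all(is.finite(xy))) {
    msgs <- c(msgs, "spot coordinates must be finite")
  }
  if (length(SummarizedExperiment::assayNames(object)) > 0L) {
    a <- SummarizedExperiment::assay(object, 1L)
    mn <- suppressWarnings(min(a))
    if (is.finite(mn) && mn < 0) {
      msgs <- c(msgs, "expression values must be non-negative")
    }
  }
  sym <- rownames(object)
  if (is.null(sym)) {
    msgs <- c(msgs, "gene symbols (rownames) are required")
  } else if (anyDuplicated(foldSymbols(sym))) {
    dup <- unique(sym[duplicated(foldSymbols(sym))])
    msgs <- c(msgs, paste0("gene symbols duplicated after case-folding: ",
                           paste(head(dup, 5L), collapse = ", ")))
  }
  if ("domain" %in% colnames(cd)) {
    d <- cd$domain
    if (!is.numeric(d) || any(!is.finite(d)) || any(d != floor(d))) {
      msgs <- c(msgs, "'domain' annotations must be integer-valued")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpatialTissue
#'
#' @param counts gene-by-spot matrix (base or [Matrix::Matrix]) of
#'   non-negative expression values, with gene symbols as rownames. Spot IDs
#'   are taken from colnames (generated as `spot_0001, ...` when absent).
#' @param coords numeric matrix or data.frame with one row per spot and two
#'   columns (x, y), in the same order as the columns of `counts`.
#' @param domains optional integer vector of ground-truth domain labels, one
#'   per spot.
#' @param is_normalized logical flag recording whether `counts` already holds
#'   normalized values; [normalizeExpression()] respects it and never
#'   normalizes twice.
#' @return A [SpatialTissue-class] object.
#' @export
#' @examples
#' cnt <- matrix(rpois(12, 2), nrow = 3,
#'               dimnames = list(c("GA", "GB", "GC"), NULL))
#' tis <- SpatialTissue(cnt, coords = cbind(x = 1:4, y = rep(0, 4)))
#' tis
SpatialTissue <- function(counts, coords, domains = NULL, is_normalized = FALSE) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) {
    stopValidation("coords must have exactly 2 columns, got ", ncol(coords))
  }
  if (nrow(coords) != ncol(counts)) {
    stopValidation("coords rows (", nrow(coords), ") must equal number of spots (",
                   ncol(counts), ")")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("spot_%04d", seq_len(ncol(counts)))
  }
  if (is.null(rownames(counts))) {
    stopValidation("counts must carry gene symbols as rownames")
  }
  cd <- S4Vectors::DataFrame(sdimx = as.numeric(coords[, 1L]),
                             sdimy = as.numeric(coords[, 2L]),
                             row.names = colnames(counts))
  if (!is.null(domains)) {
    if (length(domains) != ncol(counts)) {
      stopValidation("domains length (", length(domains),
                     ") must equal number of spots (", ncol(counts), ")")
    }
    cd$domain <- as.integer(domains)
  }
  assay_name <- if (is_normalized) "logcounts" else "counts"
  assays <- stats::setNames(list(counts), assay_name)
  sce <- SingleCellExperiment::SingleCellExperiment(assays = assays, colData = cd)
  out <- new("SpatialTissue", sce)
  S4Vectors::metadata(out)$is_normalized <- isTRUE(is_normalized)
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) {
    warning(sum(lib == 0), " spot(s) have zero total expression",
            call. = FALSE)
  }
  validObject(out)
  out
}

#' GeneEmbeddingTable: gene symbol to embedding-vector lookup
#'
#' Stores a fixed-width real vector per gene symbol, as produced by encoding
#' gene functional descriptions (e.g. NCBI gene summaries) with a text
#' embedding model. Consumed as a precomputed lookup table; symbols are
#' matched case-insensitively.
#'
#' @slot embeddings numeric matrix, one row per gene (rownames are the
#'   symbols), all entries finite.
#' @seealso [GeneEmbeddingTable()], [readGeneEmbeddingTable()],
#'   [embeddingDim()], [alignGenes()].
#' @export
setClass("GeneEmbeddingTable", representation(embeddings = "matrix"))

setValidity("GeneEmbeddingTable", function(object) {
  emb <- object@embeddings
  msgs <- character()
  if (is.null(rownames(emb))) {
    return("embedding rows must be named by gene symbol")
  }
  if (anyDuplicated(foldSymbols(rownames(emb)))) {
    dup <- unique(rownames(emb)[duplicated(foldSymbols(rownames(emb)))])
    msgs <- c(msgs, paste0("duplicate gene symbols after case-folding: ",
                           paste(head(dup, 5L), collapse = ", ")))
  }
  if (!is.numeric(emb) || any(!is.finite(emb))) {
    msgs <- c(msgs, "all embedding entries must be finite numbers")
  }
  if (length(msgs)) msgs else TRUE
})

#' @param embeddings numeric matrix with gene symbols as rownames.
#' @return A [GeneEmbeddingTable-class].
#' @rdname GeneEmbeddingTable-class
#' @export
GeneEmbeddingTable <- function(embeddings) {
  emb <- as.matrix(embeddings)
  storage.mode(emb) <- "double"
  new("GeneEmbeddingTable", embeddings = emb)
}

#' SpatialGraph: Gaussian-kernel spot proximity graph
#'
#' Holds the sparse symmetric adjacency `A` (Gaussian kernel of pairwise
#' spot distances, truncated at `tau`), its symmetrically normalized form
#' `Ahat` used by graph-convolution layers, and the kernel parameters.
#'
#' @slot A sparse symmetric adjacency with weights in `[0, 1]`.
#' @slot Ahat normalized adjacency `D^{-1/2} (A + I) D^{-1/2}`.
#' @slot sigma kernel bandwidth, in coordinate units.
#' @slot tau distance cutoff, in coordinate units.
#' @seealso [spatialGraph()], [buildAdjacency()], [normalizeAdjacency()].
#' @export
setClass("SpatialGraph",
         representation(A = "Matrix", Ahat = "Matrix",
                        sigma = "numeric", tau = "numeric"))

setValidity("SpatialGraph", function(object) {
  msgs <- character()
  if (object@sigma <= 0 || object@tau <= 0) {
    msgs <- c(msgs, "sigma and tau must be positive")
  }
  if (nrow(object@A) != ncol(object@A)) {
    msgs <- c(msgs, "A must be square")
  }
  if (length(msgs)) msgs else TRUE
})

#' PCAModel: fitted principal-component projection
#'
#' @slot center column means used for centering.
#' @slot rotation `d_in x d_out` matrix with orthonormal columns; the sign of
#'   each component is fixed so its largest-magnitude loading is positive.
#' @slot explainedVariance variance explained by each retained component,
#'   non-increasing.
#' @slot totalVariance total variance of the training data (for ratios).
#' @seealso [fitPCA()], [applyPCA()].
#' @export
setClass("PCAModel",
         representation(center = "numeric", rotation = "matrix",
                        explainedVariance = "numeric", totalVariance = "numeric"))

setValidity("PCAModel", function(object) {
  msgs <- character()
  R <- object@rotation
  if (length(object@center) != nrow(R)) {
    msgs <- c(msgs, "center length must equal rotation rows")
  }
  gram <- crossprod(R)
  if (max(abs(gram - diag(ncol(R)))) > 1e-8) {
    msgs <- c(msgs, "rotation columns must be orthonormal")
  }
  ev <- object@explainedVariance
  if (length(ev) != ncol(R) || any(ev < -1e-12) || is.unsorted(rev(ev))) {
    msgs <- c(msgs, "explainedVariance must be non-negative and non-increasing")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SpatialTissue", function(object) {
  cat("class: SpatialTissue\n")
  cat("genes:", nrow(object), " spots:", ncol(object), "\n")
  cat("normalized:", isNormalized(object), "\n")
  tr <- domainTruth(object)
  if (!is.null(tr)) {
    cat("domain annotation: K =", length(unique(tr)), "\n")
  }
  callNextMethod()
})

setMethod("show", "GeneEmbeddingTable", function(object) {
  cat("GeneEmbeddingTable:", nrow(object@embeddings), "genes x",
      ncol(object@embeddings), "dimensions\n")
  cat("symbols:", paste(head(rownames(object@embeddings), 4L), collapse = ", "),
      if (nrow(object@embeddings) > 4L) "..." else "", "\n")
})

setMethod("show", "SpatialGraph", function(object) {
  n <- nrow(object@A)
  nnz <- Matrix::nnzero(object@A)
  cat("SpatialGraph:", n, "spots,", nnz, "stored weights",
      sprintf("(sigma = %.4g, tau = %.4g)\n", object@sigma, object@tau))
})

setMethod("show", "PCAModel", function(object) {
  cat("PCAModel:", nrow(object@rotation), "->", ncol(object@rotation),
      "dims;", sprintf("%.1f%% variance retained\n",
                       100 * sum(object@explainedVariance) / object@totalVariance))
})
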