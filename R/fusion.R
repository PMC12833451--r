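#' Fusion configuration
#'
#' Weights and conventions for combining the spatial and functional
#' embedding streams. With the default `alpha = beta = 0.5` the two streams
#' contribute equally; `(1, 0)` degenerates to the expression-only pipeline
#' and `(0, 1)` to the functional-only pipeline.
#'
#' @param alpha weight of the spatial stream (>= 0).
#' @param beta weight of the functional stream (>= 0); `alpha + beta > 0`.
#' @param standardize standardize each stream column-wise before the
#'   weighted sum (default TRUE): the two streams have incommensurate raw
#'   scales, and the sum is only meaningful after calibration.
#' @param functional_source which expression matrix feeds the functional
#'   stream: `"normalized"` (default) or `"raw"` counts.
#' @return validated list of class `"FusionConfig"`.
#' @export
fusionConfig <- function(alpha = 0.5, beta = 0.5, standardize = TRUE,
                         functional_source = c("normalized", "raw")) {
  functional_source <- match.arg(functional_source)
  if (alpha < 0 || beta < 0) stopValidation("alpha and beta must be >= 0")
  if (alpha + beta <= 0) stopValidation("alpha + beta must be > 0")
  structure(list(alpha = alpha, beta = beta, standardize = isTRUE(standardize),
                 functional_source = functional_source),
            class = "FusionConfig")
}

#' Functional spot embedding
#'
#' Multiplies the spot-by-gene expression matrix with the aligned gene
#' feature matrix: `H = X %*% F`. Each spot's functional embedding is the
#' expression-weighted sum of its genes' description-embedding vectors, so
#' expression levels implicitly weigh each functional dimension.
#'
#' @param X n_spots x m' expression matrix restricted to the aligned genes
#'   (same order as the rows of `F_matrix`).
#' @param F_matrix m' x d_llm gene feature matrix (e.g. from
#'   [alignGenes()]`$F_matrix`).
#' @return dense n_spots x d_llm embedding matrix.
#' @export
functionalEmbed <- function(X, F_matrix) {
  if (ncol(X) != nrow(F_matrix)) {
    stopValidation("X gene count (", ncol(X), ") does not match F rows (",
                   nrow(F_matrix), ")")
  }
  out <- as.matrix(X %*% F_matrix)
  rownames(out) <- rownames(X)
  out
}

#' Standardize an embedding stream
#'
#' Centers each column to mean 0 and scales to unit population variance
#' (divisor n). Constant columns become all-zero. Idempotent.
#'
#' @param H numeric embedding matrix, spots in rows.
#' @return standardized matrix of the same shape.
#' @export
standardizeStream <- function(H) {
  H <- asMatrix(H)
  if (nrow(H) < 2L) stopValidation("need at least 2 spots to standardize")
  mu <- colMeans(H)
  Hc <- sweep(H, 2L, mu)
  s <- sqrt(colMeans(Hc^2))
  s[s == 0] <- 1   # constant columns -> centered zeros stay zero
  sweep(Hc, 2L, s, "/")
}

#' Weighted fusion of the two embedding streams
#'
#' Computes `Z = alpha * H_spatial + beta * H_functional_pca`, optionally
#' standardizing each stream first ([standardizeStream()]). Both streams
#' must already share the latent width (reduce the functional stream with
#' [applyPCA()] first).
#'
#' @param H_spatial n x d latent embedding from [trainSpatialEncoder()].
#' @param H_functional_pca n x d reduced functional embedding.
#' @param config a [fusionConfig()].
#' @return fused n x d embedding matrix.
#' @export
fuseEmbeddings <- function(H_spatial, H_functional_pca, config = fusionConfig()) {
  H_spatial <- asMatrix(H_spatial); H_functional_pca <- asMatrix(H_functional_pca)
  if (!identical(dim(H_spatial), dim(H_functional_pca))) {
    stopValidation("stream shapes differ (", nrow(H_spatial), "x", ncol(H_spatial),
                   " vs ", nrow(H_functional_pca), "x", ncol(H_functional_pca),
                   "); apply applyPCA() to the functional stream first")
  }
  if (config$standardize) {
    H_spatial <- standardizeStream(H_spatial)
    H_functional_pca <- standardizeStream(H_functional_pca)
  }
  config$alpha * H_spatial + config$beta * H_functional_pca
}

#' Run the full fusion pipeline
#'
#' End-to-end driver: normalizes expression, builds the Gaussian-kernel
#' spatial graph, trains the graph-convolutional autoencoder (spatial
#' stream), aligns genes with the embedding table and computes the
#' functional stream `X %*% F`, reduces it to the latent width by PCA, fuses
#' the two streams with the configured weights, and clusters the fused
#' embedding into spatial domains.
#'
#' @param tissue a [SpatialTissue-class] (raw counts or normalized).
#' @param table a [GeneEmbeddingTable-class].
#' @param encoder_config an [encoderConfig()].
#' @param fusion_config a [fusionConfig()].
#' @param cluster_config a [clusterConfig()]; when its `n_clusters` is `NULL`
#'   the number of distinct truth labels is used (an error if no truth).
#' @param n_hvg highly-variable-gene count for [normalizeExpression()].
#' @param sigma,tau,k_neighbors spatial graph settings ([spatialGraph()]).
#' @param missing_policy gene alignment policy ([alignGenes()]).
#' @param seed optional top-level seed; when given, stage seeds for the
#'   encoder and clustering are derived from it via [deriveSeed()] and
#'   override the per-config seeds.
#' @return A [SpatialTissue-class] with reduced dimensions `"spatial"`,
#'   `"functionalPCA"` and `"fused"`, predicted labels in
#'   `colData()$domain_pred`, and a run report (graph parameters, dropped
#'   genes, seeds, per-stage dimensions, ARI when truth is present) in
#'   `metadata()$spaFuse`.
#' @seealso [predictedDomains()], [fusedEmbedding()], [runReport()].
#' @export
runSpaFuse <- function(tissue, table,
                       encoder_config = encoderConfig(),
                       fusion_config = fusionConfig(),
                       cluster_config = clusterConfig(),
                       n_hvg = 3000L, sigma = NULL, tau = NULL,
                       k_neighbors = 6L, missing_policy = "drop",
                       seed = NULL) {
  if (!is.null(seed)) {
    encoder_config$seed <- deriveSeed(seed, "encoder")
    cluster_config$seed <- deriveSeed(seed, "cluster")
  }
  norm <- normalizeExpression(tissue, n_hvg = n_hvg)
  graph <- spatialGraph(spatialCoords(norm), sigma = sigma, tau = tau,
                        k_neighbors = k_neighbors)
  Xn <- as.matrix(spotExpression(norm))
  enc <- trainSpatialEncoder(Xn, graph, encoder_config)
  H_st <- enc$embedding

  func_src <- if (fusion_config$functional_source == "normalized") norm else tissue
  aln <- suppressWarnings(alignGenes(geneSymbols(func_src), table,
                                     missing_policy = missing_policy))
  Xf <- spotExpression(func_src)[, aln$kept_gene_indices, drop = FALSE]
  H_llm <- functionalEmbed(Xf, aln$F_matrix)
  pca <- fitPCA(H_llm, d_out = encoder_config$d_latent)
  H_pca <- applyPCA(pca, H_llm)
  Z <- fuseEmbeddings(H_st, H_pca, fusion_config)

  truth <- domainTruth(tissue)
  if (is.null(cluster_config$n_clusters)) {
    if (is.null(truth)) {
      stopValidation("n_clusters not set and tissue has no truth labels")
    }
    cluster_config$n_clusters <- length(unique(truth))
  }
  labels <- clusterEmbedding(Z, cluster_config)

  out <- tissue
  SingleCellExperiment::reducedDims(out) <- list(spatial = H_st,
                                                 functionalPCA = H_pca,
                                                 fused = Z)
  SummarizedExperiment::colData(out)$domain_pred <- labels
  report <- list(
    sigma = graph@sigma, tau = graph@tau,
    n_spots = ncol(tissue), n_genes_raw = nrow(tissue),
    n_genes_normalized = nrow(norm), n_genes_aligned = length(aln$kept_gene_indices),
    dropped_genes = aln$dropped_symbols,
    dims = list(spatial = ncol(H_st), functional = ncol(H_llm),
                functional_pca = ncol(H_pca), fused = ncol(Z)),
    alpha = fusion_config$alpha, beta = fusion_config$beta,
    functional_stream = if (fusion_config$beta == 0) "disabled" else "enabled",
    spatial_stream = if (fusion_config$alpha == 0) "disabled" else "enabled",
    seeds = list(encoder = enc$config$seed, cluster = cluster_config$seed),
    cluster_method = cluster_config$method,
    n_clusters = cluster_config$n_clusters,
    final_loss = enc$trace[length(enc$trace)]
  )
  if (!is.null(truth)) report$ari <- adjustedRandIndex(labels, truth)
  S4Vectors::metadata(out)$spaFuse <- report
  out
}

#' Predicted domain labels from a fitted run
#'
#' @param x a [SpatialTissue-class] returned by [runSpaFuse()].
#' @return integer labels in `[0, K)`.
#' @export
predictedDomains <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"domain_pred" %in% colnames(cd)) {
    stopValidation("no predictions present; run runSpaFuse() first")
  }
  as.integer(cd$domain_pred)
}

#' Fused embedding from a fitted run
#'
#' @param x a [SpatialTissue-class] returned by [runSpaFuse()].
#' @return n x d fused embedding matrix.
#' @export
fusedEmbedding <- function(x) {
  SingleCellExperiment::reducedDim(x, "fused")
}

#' Run report from a fitted run
#'
#' @param x a [SpatialTissue-class] returned by [runSpaFuse()].
#' @return list with graph parameters, stage dimensions, seeds, dropped
#'   genes and (when truth labels exist) the ARI.
#' @export
runReport <- function(x) {
  S4Vectors::metadata(x)$spaFuse
}
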