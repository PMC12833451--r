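#' @importFrom mclust Mclust mclustBIC
NULL

#' Clustering configuration
#'
#' @param method `"kmeans"`, `"louvain"` or `"gmm"` (full-covariance
#'   Gaussian mixture, the mclust-style model-based option).
#' @param n_clusters number of domains for kmeans/gmm; defaults to the
#'   number of distinct truth labels inside [runSpaFuse()]/[benchmarkQuality()].
#' @param resolution Louvain modularity resolution.
#' @param n_init number of seeded restarts for kmeans (best objective kept).
#' @param seed integer seed; identical seeds give identical labels.
#' @return validated list of class `"ClusterConfig"`.
#' @export
clusterConfig <- function(method = c("kmeans", "louvain", "gmm"),
                          n_clusters = NULL, resolution = 1,
                          n_init = 10L, seed = 1L) {
  method <- match.arg(method)
  if (!is.null(n_clusters) && n_clusters < 1L) {
    stopValidation("n_clusters must be >= 1")
  }
  structure(list(method = method, n_clusters = n_clusters,
                 resolution = resolution, n_init = as.integer(n_init),
                 seed = as.integer(seed)),
            class = "ClusterConfig")
}

#' Cluster a spot embedding into domains
#'
#' Assigns each spot to a domain by clustering the embedding rows. kmeans
#' takes the best of `n_init` seeded restarts by within-cluster sum of
#' squares; gmm fits a full-covariance Gaussian mixture; louvain builds a
#' 15-nearest-neighbor graph with inverse-distance similarity weights and
#' maximizes modularity (its cluster count is data-driven, not `n_clusters`).
#'
#' @param Z n x d embedding matrix with finite entries.
#' @param config a [clusterConfig()].
#' @return integer labels in `[0, K)`, one per spot.
#' @export
clusterEmbedding <- function(Z, config = clusterConfig()) {
  Z <- asMatrix(Z)
  if (any(!is.finite(Z))) stopValidation("embedding contains non-finite values")
  n <- nrow(Z)
  k <- config$n_clusters
  if (config$method %in% c("kmeans", "gmm")) {
    if (is.null(k)) stopValidation("n_clusters is required for ", config$method)
    if (k > n) stopValidation("n_clusters = ", k, " exceeds n_spots = ", n)
  }
  labels <- switch(config$method,
    kmeans = {
      if (k == 1L) rep(0L, n) else withSeed(config$seed, {
        km <- suppressWarnings(
          kmeans(Z, centers = k, nstart = config$n_init, iter.max = 200L))
        as.integer(km$cluster) - 1L
      })
    },
    gmm = {
      if (k == 1L) rep(0L, n) else withSeed(config$seed, {
        fit <- NULL
        for (mod in c("VVV", "EEE", "EII")) {
          fit <- tryCatch(
            mclust::Mclust(Z, G = k, modelNames = mod, verbose = FALSE),
            error = function(e) NULL)
          if (!is.null(fit)) break
        }
        if (is.null(fit)) stopNumerical("Gaussian mixture failed to fit")
        as.integer(fit$classification) - 1L
      })
    },
    louvain = {
      g <- knnSimilarityGraph(Z, k = min(15L, n - 1L))
      withSeed(config$seed, {
        cl <- igraph::cluster_louvain(g, resolution = config$resolution)
        as.integer(igraph::membership(cl)) - 1L
      })
    })
  labels
}

## undirected kNN graph with weights 1 / (1 + Euclidean distance)
knnSimilarityGraph <- function(Z, k) {
  n <- nrow(Z)
  d <- as.matrix(dist(Z))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1L)]
    from <- c(from, rep(i, k)); to <- c(to, nb)
    w <- c(w, 1 / (1 + d[i, nb]))
  }
  el <- cbind(pmin(from, to), pmax(from, to))
  keep <- !duplicated(el)
  igraph::graph_from_data_frame(
    data.frame(from = el[keep, 1L], to = el[keep, 2L], weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement,
#' `ARI = (RI - E[RI]) / (max(RI) - E[RI])`, computed from the contingency
#' table of the two labelings. Equals 1 for identical partitions (up to
#' label renaming), is near 0 for random assignments, and is symmetric in
#' its arguments.
#'
#' @param pred,truth label vectors of equal length (n >= 2); any label
#'   coding is accepted.
#' @return scalar ARI, at most 1.
#' @export
#' @examples
#' adjustedRandIndex(c(0, 0, 1, 1), c(1, 1, 0, 0))  # 1: same partition
adjustedRandIndex <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stopValidation("label lengths differ: ", length(pred), " vs ", length(truth))
  }
  n <- length(pred)
  if (n < 2L) stopValidation("need at least 2 items")
  tab <- table(pred, truth)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  npairs <- choose(n, 2)
  expected <- a * b / npairs
  maxidx <- (a + b) / 2
  if (maxidx == expected) return(1)   # both partitions trivial (all-singleton/all-one)
  (sum_ij - expected) / (maxidx - expected)
}

#' Benchmark fusion strategies across quality levels
#'
#' Reproduces the method-by-quality experimental grid on a tissue with
#' ground-truth annotations: for each quality level the counts are masked
#' once (fixed level seed, so run-to-run variance reflects the method, not
#' the mask), and for each run the spatial encoder is retrained with a
#' derived seed. All fusion strategies share the trained encoder of a run:
#' `expression_only` is the spatial stream alone (weights 1, 0),
#' `functional_only` the reduced functional stream alone (0, 1),
#' `concatenation` the column-standardized side-by-side concatenation at
#' width `2 * d_latent`, and `weighted` the configured weighted sum.
#'
#' @param tissue a [SpatialTissue-class] with truth labels.
#' @param table a [GeneEmbeddingTable-class].
#' @param levels quality levels to evaluate (default Q0..Q4).
#' @param strategies subset of
#'   `c("expression_only", "functional_only", "concatenation", "weighted")`.
#' @param n_runs runs per cell; mean and standard deviation are reported.
#' @param seed top-level seed; all stage seeds derive from it.
#' @param encoder_config,fusion_config,cluster_config stage settings; the
#'   `alpha`/`beta` of `fusion_config` define the `weighted` strategy.
#' @param n_hvg,k_neighbors forwarded to the pipeline stages.
#' @return data.frame with columns `strategy`, `level`, `mean_ari`,
#'   `sd_ari`, `n_runs`. The per-run ARIs are attached as attribute
#'   `"runs"` (long data.frame with columns `strategy`, `level`, `run`,
#'   `ari`).
#' @seealso [formatBenchmarkTable()] for the text rendering.
#' @export
benchmarkQuality <- function(tissue, table,
                             levels = names(qualityLevels()),
                             strategies = c("expression_only", "functional_only",
                                            "concatenation", "weighted"),
                             n_runs = 10L, seed = 1L,
                             encoder_config = encoderConfig(),
                             fusion_config = fusionConfig(),
                             cluster_config = clusterConfig(),
                             n_hvg = 3000L, k_neighbors = 6L) {
  truth <- domainTruth(tissue)
  if (is.null(truth)) stopValidation("benchmark requires truth labels")
  strategies <- match.arg(strategies, several.ok = TRUE)
  levels <- match.arg(levels, names(qualityLevels()), several.ok = TRUE)
  K <- length(unique(truth))
  grid <- qualityGrid(tissue, seed = deriveSeed(seed, "mask"), levels = levels)
  rows <- list()
  run_rows <- list()
  for (lv in levels) {
    degraded <- grid[[lv]]
    norm <- suppressWarnings(normalizeExpression(degraded, n_hvg = n_hvg))
    graph <- spatialGraph(spatialCoords(norm), k_neighbors = k_neighbors)
    Xn <- as.matrix(spotExpression(norm))
    aln <- suppressWarnings(alignGenes(geneSymbols(norm), table))
    H_llm <- functionalEmbed(
      spotExpression(norm)[, aln$kept_gene_indices, drop = FALSE], aln$F_matrix)
    pca <- fitPCA(H_llm, d_out = encoder_config$d_latent)
    H_pca <- applyPCA(pca, H_llm)
    ari <- matrix(NA_real_, nrow = n_runs, ncol = length(strategies),
                  dimnames = list(NULL, strategies))
    for (r in seq_len(n_runs)) {
      ecfg <- encoder_config
      ecfg$seed <- deriveSeed(seed, "encoder", lv, r)
      enc <- trainSpatialEncoder(Xn, graph, ecfg)
      embeddings <- strategyEmbeddings(enc$embedding, H_pca, fusion_config,
                                       strategies)
      for (s in strategies) {
        ccfg <- cluster_config
        ccfg$n_clusters <- K
        ccfg$seed <- deriveSeed(seed, "cluster", lv, r, s)
        lab <- clusterEmbedding(embeddings[[s]], ccfg)
        ari[r, s] <- adjustedRandIndex(lab, truth)
        run_rows[[length(run_rows) + 1L]] <- data.frame(
          strategy = s, level = lv, run = r, ari = ari[r, s])
      }
    }
    for (s in strategies) {
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = s, level = lv, mean_ari = mean(ari[, s]),
        sd_ari = if (n_runs > 1L) sd(ari[, s]) else 0,
        n_runs = n_runs)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "runs") <- do.call(rbind, run_rows)
  out
}

strategyEmbeddings <- function(H_st, H_pca, fusion_config, strategies) {
  out <- list()
  for (s in strategies) {
    out[[s]] <- switch(s,
      expression_only = fuseEmbeddings(H_st, H_pca,
        fusionConfig(alpha = 1, beta = 0,
                     standardize = fusion_config$standardize)),
      functional_only = fuseEmbeddings(H_st, H_pca,
        fusionConfig(alpha = 0, beta = 1,
                     standardize = fusion_config$standardize)),
      concatenation = cbind(standardizeStream(H_st), standardizeStream(H_pca)),
      weighted = fuseEmbeddings(H_st, H_pca, fusion_config))
  }
  out
}

#' Render a benchmark report as a text table
#'
#' Formats the strategy-by-quality grid with `mean±sd` cells, mirroring the
#' usual presentation of quality-degradation benchmarks.
#'
#' @param report data.frame from [benchmarkQuality()].
#' @return character vector of lines (also printed invisibly by `cat`-ing).
#' @export
formatBenchmarkTable <- function(report) {
  levels <- unique(report$level)
  strategies <- unique(report$strategy)
  header <- sprintf("%-18s %s", "strategy",
                    paste(sprintf("%-12s", levels), collapse = " "))
  lines <- header
  for (s in strategies) {
    cells <- vapply(levels, function(lv) {
      row <- report[report$strategy == s & report$level == lv, ]
      if (nrow(row) == 0L) return(sprintf("%-12s", "-"))
      sprintf("%-12s", sprintf("%.3f±%.3f", row$mean_ari, row$sd_ari))
    }, character(1))
    lines <- c(lines, sprintf("%-18s %s", s, paste(cells, collapse = " ")))
  }
  lines
}
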