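#' Align dataset genes with an embedding table
#'
#' Matches the tissue's gene symbols against the embedding table
#' (case-insensitively, whitespace-stripped) and assembles the gene feature
#' matrix in dataset gene order. Under `missing_policy = "drop"` the genes
#' absent from the table are removed from the functional stream; under
#' `"zero"` every gene is kept and absent genes receive all-zero vectors
#' (equivalent to dropping them whenever they are unexpressed).
#'
#' @param genes character vector of gene symbols, or a [SpatialTissue-class].
#' @param table a [GeneEmbeddingTable-class].
#' @param missing_policy `"drop"` (default) or `"zero"`.
#' @return list with `kept_gene_indices` (1-based indices into the input
#'   genes, order preserved), `F_matrix` (one row per kept gene), and
#'   `dropped_symbols`.
#' @export
#' @examples
#' tab <- GeneEmbeddingTable(matrix(1:6, 2, dimnames = list(c("A", "C"), NULL)))
#' alignGenes(c("a", "B", "C"), tab)$kept_gene_indices  # 1, 3 via case-fold
alignGenes <- function(genes, table, missing_policy = c("drop", "zero")) {
  missing_policy <- match.arg(missing_policy)
  if (is(genes, "SpatialTissue")) genes <- geneSymbols(genes)
  emb <- embeddingMatrix(table)
  idx <- match(foldSymbols(genes), foldSymbols(rownames(emb)))
  dropped <- genes[is.na(idx)]
  if (missing_policy == "drop") {
    kept <- which(!is.na(idx))
    if (length(kept) == 0L) {
      stopValidation("no overlapping genes between dataset and embedding table")
    }
    Fm <- emb[idx[kept], , drop = FALSE]
    rownames(Fm) <- genes[kept]
  } else {
    kept <- seq_along(genes)
    Fm <- matrix(0, nrow = length(genes), ncol = ncol(emb),
                 dimnames = list(genes, colnames(emb)))
    hit <- which(!is.na(idx))
    Fm[hit, ] <- emb[idx[hit], , drop = FALSE]
  }
  if (length(dropped)) {
    warning(length(dropped), " gene(s) absent from the embedding table: ",
            paste(head(dropped, 20L), collapse = ", "),
            if (length(dropped) > 20L) ", ..." else "", call. = FALSE)
  }
  list(kept_gene_indices = kept, F_matrix = Fm, dropped_symbols = dropped)
}

#' Fit a principal-component projection
#'
#' Deterministic full singular-value decomposition of the centered data; the
#' sign of each component is fixed so that its largest-magnitude loading is
#' positive, making the projection reproducible across platforms.
#'
#' @param H numeric matrix, observations in rows.
#' @param d_out number of components to retain; at most `min(nrow, ncol)`.
#' @param seed accepted for interface stability; the exact decomposition is
#'   deterministic and does not consume randomness.
#' @return A [PCAModel-class].
#' @export
fitPCA <- function(H, d_out, seed = NULL) {
  H <- asMatrix(H)
  n <- nrow(H); d_in <- ncol(H)
  if (d_out > min(n, d_in)) {
    stopValidation("d_out = ", d_out, " exceeds min(n = ", n,
                   ", d_in = ", d_in, ")")
  }
  ctr <- colMeans(H)
  Hc <- sweep(H, 2L, ctr)
  sv <- La.svd(Hc, nu = 0L, nv = min(n, d_in))
  rot <- t(sv$vt)[, seq_len(d_out), drop = FALSE]
  for (j in seq_len(d_out)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  ev <- (sv$d^2) / (n - 1L)
  new("PCAModel", center = ctr, rotation = rot,
      explainedVariance = ev[seq_len(d_out)], totalVariance = sum(ev))
}

#' Project data with a fitted PCA model
#'
#' Centers with the model's training mean and projects onto the retained
#' components.
#'
#' @param model a [PCAModel-class].
#' @param H numeric matrix with the same column width the model was fit on.
#' @return `nrow(H) x d_out` score matrix.
#' @export
applyPCA <- function(model, H) {
  H <- asMatrix(H)
  if (ncol(H) != nrow(model@rotation)) {
    stopValidation("input width ", ncol(H), " does not match model width ",
                   nrow(model@rotation))
  }
  sweep(H, 2L, model@center) %*% model@rotation
}

#' Explained-variance ratios of a PCA model
#'
#' @param model a [PCAModel-class].
#' @return fraction of total variance captured by each retained component.
#' @export
explainedVarianceRatio <- function(model) {
  model@explainedVariance / model@totalVariance
}
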