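#' Build a Gaussian-kernel spatial adjacency matrix
#'
#' Edge weight between spots i and j is
#' `exp(-||c_i - c_j||^2 / (2 sigma^2))` when their Euclidean distance is at
#' most `tau`, and 0 otherwise. The diagonal is 1 (distance zero is always
#' within the cutoff). Weights depend only on relative distances, so the
#' construction is invariant to translation and rotation of the coordinates.
#'
#' @param coords n x 2 matrix of planar spot coordinates.
#' @param sigma kernel bandwidth (> 0), coordinate units.
#' @param tau distance cutoff (> 0), coordinate units.
#' @return sparse symmetric `dgCMatrix` with entries in `[0, 1]`.
#' @seealso [autoBandwidth()] for data-driven `sigma`/`tau`,
#'   [normalizeAdjacency()].
#' @export
#' @examples
#' A <- buildAdjacency(cbind(0:3, 0), sigma = 0.5, tau = 1.5)
#' A[1, 2]  # exp(-1/(2*0.25)) = exp(-2)
buildAdjacency <- function(coords, sigma, tau) {
  coords <- as.matrix(coords)
  if (!is.numeric(sigma) || sigma <= 0) stopValidation("sigma must be > 0")
  if (!is.numeric(tau) || tau <= 0) stopValidation("tau must be > 0")
  if (any(!is.finite(coords))) stopValidation("coordinates must be finite")
  n <- nrow(coords)
  chunk <- 1024L
  ii <- list(); jj <- list(); xx <- list(); b <- 1L
  tau2 <- tau^2
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    # squared distances from this block to all spots
    d2 <- outer(rowSums(coords[rows, , drop = FALSE]^2), rowSums(coords^2), "+") -
      2 * coords[rows, , drop = FALSE] %*% t(coords)
    d2[d2 < 0] <- 0
    hit <- which(d2 <= tau2, arr.ind = TRUE)
    ii[[b]] <- rows[hit[, 1L]]
    jj[[b]] <- hit[, 2L]
    xx[[b]] <- exp(-d2[hit] / (2 * sigma^2))
    b <- b + 1L
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  A <- (A + Matrix::t(A)) / 2  # enforce exact symmetry against fp asymmetry
  Matrix::diag(A) <- 1
  methods::as(A, "CsparseMatrix")
}

#' Data-driven kernel bandwidth and cutoff
#'
#' Sets the cutoff to 1.05 times the mean distance to the k-th nearest
#' neighbor (so the typical local neighborhood is just inside it) and the
#' bandwidth to half the cutoff. The default `k_neighbors = 6` targets the
#' hexagonal first shell of Visium-style lattices.
#'
#' @param coords n x 2 matrix of spot coordinates.
#' @param k_neighbors which nearest neighbor defines the local scale.
#' @return list with elements `sigma` and `tau`.
#' @export
autoBandwidth <- function(coords, k_neighbors = 6L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n <= k_neighbors) {
    stopValidation("need more than k_neighbors = ", k_neighbors, " spots, got ", n)
  }
  kd <- numeric(n)
  chunk <- 1024L
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    d2 <- outer(rowSums(coords[rows, , drop = FALSE]^2), rowSums(coords^2), "+") -
      2 * coords[rows, , drop = FALSE] %*% t(coords)
    d2[d2 < 0] <- 0
    for (r in seq_along(rows)) {
      dr <- sort(d2[r, ])[k_neighbors + 1L]  # +1 skips self at distance 0
      kd[rows[r]] <- sqrt(dr)
    }
  }
  if (all(kd == 0)) {
    stopValidation("all coordinates identical; cannot derive a bandwidth")
  }
  tau <- 1.05 * mean(kd)
  list(sigma = tau / 2, tau = tau)
}

#' Symmetrically normalize an adjacency matrix
#'
#' Computes `Ahat = D^{-1/2} (A + I) D^{-1/2}` where `D` is the degree of
#' `A + I` (default), or the same normalization of `A` alone when
#' `add_self_loops = FALSE`. This is the propagation operator of
#' graph-convolution layers; its spectral radius is at most 1.
#'
#' @param A symmetric non-negative (sparse) adjacency.
#' @param add_self_loops add the identity before normalizing (default TRUE)
#'   so each node retains its own features during propagation.
#' @return sparse symmetric normalized adjacency.
#' @export
normalizeAdjacency <- function(A, add_self_loops = TRUE) {
  A <- methods::as(A, "CsparseMatrix")
  if (nrow(A) != ncol(A)) stopValidation("A must be square")
  At <- if (add_self_loops) A + Matrix::Diagonal(nrow(A)) else A
  deg <- Matrix::rowSums(At)
  if (any(deg <= 0)) {
    stopValidation(sum(deg <= 0), " node(s) have zero degree; ",
                   "consider add_self_loops = TRUE")
  }
  Dinv <- Matrix::Diagonal(x = 1 / sqrt(deg))
  methods::as(Dinv %*% At %*% Dinv, "CsparseMatrix")
}

#' Build the full spatial graph for a tissue
#'
#' Convenience wrapper: derives `sigma`/`tau` via [autoBandwidth()] when not
#' supplied, builds the Gaussian-kernel adjacency and its normalized form.
#'
#' @param coords n x 2 coordinate matrix or a [SpatialTissue-class].
#' @param sigma,tau kernel parameters; both derived automatically when NULL.
#' @param k_neighbors passed to [autoBandwidth()].
#' @param add_self_loops passed to [normalizeAdjacency()].
#' @return A [SpatialGraph-class].
#' @export
spatialGraph <- function(coords, sigma = NULL, tau = NULL, k_neighbors = 6L,
                         add_self_loops = TRUE) {
  if (is(coords, "SpatialTissue")) coords <- spatialCoords(coords)
  if (is.null(sigma) || is.null(tau)) {
    bw <- autoBandwidth(coords, k_neighbors)
    if (is.null(sigma)) sigma <- bw$sigma
    if (is.null(tau)) tau <- bw$tau
  }
  A <- buildAdjacency(coords, sigma, tau)
  new("SpatialGraph", A = A, Ahat = normalizeAdjacency(A, add_self_loops),
      sigma = sigma, tau = tau)
}

#' Export graph edges as a TSV edge list
#'
#' Writes the upper triangle (i < j) of the adjacency as columns
#' `i`, `j`, `weight` for external inspection.
#'
#' @param graph a [SpatialGraph-class] or sparse adjacency matrix.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
exportEdgeList <- function(graph, path) {
  A <- if (is(graph, "SpatialGraph")) graph@A else graph
  tm <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
  keep <- tm@i < tm@j
  df <- data.frame(i = tm@i[keep] + 1L, j = tm@j[keep] + 1L,
                   weight = tm@x[keep])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
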