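#' Quality-level mask fractions
#'
#' The degradation protocol zeroes a fixed fraction of the non-zero
#' expression entries: Q0 leaves the data untouched, and each subsequent
#' level halves the surviving non-zeros (50%, 75%, 87.5%, 93.75% masked).
#'
#' @return named numeric vector `c(Q0 = 0, Q1 = 0.5, Q2 = 0.75,
#'   Q3 = 0.875, Q4 = 0.9375)`.
#' @export
qualityLevels <- function() {
  c(Q0 = 0, Q1 = 0.5, Q2 = 0.75, Q3 = 0.875, Q4 = 0.9375)
}

maskSparse <- function(x, fraction, seed) {
  if (fraction < 0 || fraction > 1) {
    stopValidation("fraction must be in [0, 1], got ", fraction)
  }
  xs <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
  xs <- Matrix::drop0(xs)
  nnz <- length(xs@x)
  k <- floor(fraction * nnz)
  if (k == 0L) return(x)   # untouched entries stay bit-identical
  hit <- withSeed(seed, sample.int(nnz, k))
  xs@x[hit] <- 0
  Matrix::drop0(xs)
}

#' @rdname maskExpression
#' @export
setMethod("maskExpression", "Matrix", function(x, fraction, seed) {
  maskSparse(x, fraction, seed)
})

#' @rdname maskExpression
#' @export
setMethod("maskExpression", "matrix", function(x, fraction, seed) {
  if (fraction < 0 || fraction > 1) {
    stopValidation("fraction must be in [0, 1], got ", fraction)
  }
  if (floor(fraction * sum(x != 0)) == 0) return(x)  # bit-identical no-op
  out <- as.matrix(maskSparse(Matrix::Matrix(x, sparse = TRUE), fraction, seed))
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname maskExpression
#' @export
setMethod("maskExpression", "SpatialTissue", function(x, fraction, seed) {
  a <- maskSparse(SummarizedExperiment::assay(x, 1L), fraction, seed)
  dimnames(a) <- dimnames(x)
  suppressWarnings(SpatialTissue(a, coords = spatialCoords(x),
                                 domains = domainTruth(x),
                                 is_normalized = isNormalized(x)))
})

#' @rdname expressionDensity
#' @export
setMethod("expressionDensity", "Matrix", function(x) {
  Matrix::nnzero(x) / prod(dim(x))
})

#' @rdname expressionDensity
#' @export
setMethod("expressionDensity", "matrix", function(x) {
  sum(x != 0) / length(x)
})

#' @rdname expressionDensity
#' @export
setMethod("expressionDensity", "SpatialTissue", function(x) {
  expressionDensity(SummarizedExperiment::assay(x, 1L))
})

#' Generate the full quality-degradation grid
#'
#' Produces one degraded copy of the input per quality level. By default
#' each level is masked independently from the original matrix with a
#' level-specific derived seed. With `nested = TRUE` the masks are nested
#' (the entries zeroed at one level stay zeroed at all worse levels): a
#' single random permutation of the non-zero entries is drawn and level k
#' zeroes its first `floor(f_k * nnz)` positions.
#'
#' @param x a matrix, sparse [Matrix::Matrix], or [SpatialTissue-class].
#' @param seed integer seed; level seeds are derived via [deriveSeed()].
#' @param levels subset of `c("Q0", ..., "Q4")` to produce.
#' @param nested logical; nested masks instead of independent ones.
#' @return named list of degraded objects, one per requested level
#'   (`Q0` is the input itself).
#' @export
qualityGrid <- function(x, seed = 1L, levels = names(qualityLevels()),
                        nested = FALSE) {
  fr <- qualityLevels()
  levels <- match.arg(levels, names(fr), several.ok = TRUE)
  out <- stats::setNames(vector("list", length(levels)), levels)
  if (nested) {
    nnz0 <- if (is(x, "SpatialTissue")) {
      Matrix::nnzero(SummarizedExperiment::assay(x, 1L))
    } else if (is(x, "Matrix")) Matrix::nnzero(x) else sum(x != 0)
    perm <- withSeed(deriveSeed(seed, "nested"), sample.int(nnz0))
  }
  for (lv in levels) {
    f <- fr[[lv]]
    if (f == 0) {
      out[[lv]] <- x
    } else if (nested) {
      out[[lv]] <- maskWithOrder(x, floor(f * nnz0), perm)
    } else {
      out[[lv]] <- maskExpression(x, f, seed = deriveSeed(seed, lv))
    }
  }
  out
}

## zero the first k entries of a fixed permutation of the non-zero positions
maskWithOrder <- function(x, k, perm) {
  if (is(x, "SpatialTissue")) {
    a <- SummarizedExperiment::assay(x, 1L)
    a <- maskWithOrder(a, k, perm)
    dimnames(a) <- dimnames(x)
    return(suppressWarnings(SpatialTissue(a, coords = spatialCoords(x),
                                          domains = domainTruth(x),
                                          is_normalized = isNormalized(x))))
  }
  was_dense <- !is(x, "Matrix")
  sm <- methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                                "CsparseMatrix"), "generalMatrix")
  sm <- Matrix::drop0(sm)
  if (k > 0L) {
    sm@x[perm[seq_len(k)]] <- 0
    sm <- Matrix::drop0(sm)
  }
  if (was_dense) {
    out <- as.matrix(sm); dimnames(out) <- dimnames(x); out
  } else sm
}
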