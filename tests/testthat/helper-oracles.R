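# Independent brute-force oracles used to validate the algebraic cores.
# These deliberately avoid the code paths they check.

# ARI by explicit enumeration of all n*(n-1)/2 item pairs.
ariPairOracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  np <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / np
  maxidx <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxidx == expected) return(1)
  (n11 - expected) / (maxidx - expected)
}

# All set partitions of 1..n as label vectors (restricted-growth strings).
allPartitions <- function(n) {
  out <- list()
  rec <- function(labels, used) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (v in 0:used) rec(c(labels, v), max(used, v + 1L))
  }
  rec(integer(0), 0L)
  out
}

# Triple scalar loop matrix product.
matmulOracle <- function(A, B) {
  n <- nrow(A); m <- ncol(B); p <- ncol(A)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- 0
      for (k in seq_len(p)) s <- s + A[i, k] * B[k, j]
      out[i, j] <- s
    }
  }
  out
}

# Small synthetic tissue for fast pipeline tests.
smallTissue <- function(seed = 1L, signal = 5) {
  makeTissue(tissueSpec(grid_rows = 20L, grid_cols = 20L, n_domains = 4L,
                        n_genes = 100L, program_size = 10L, signal = signal,
                        seed = seed))
}

smallTable <- function(tissue, seed = 2L, dim = 32L) {
  makeEmbeddingTable(embeddingSpec(dim = dim, seed = seed),
                     S4Vectors::metadata(tissue)$programs)
}

# A tiny 3-spot x 2-gene tissue with known values.
toyTissue <- function() {
  cnt <- Matrix::Matrix(matrix(c(1, 0, 2,
                                 0, 3, 4), nrow = 2, byrow = TRUE,
                               dimnames = list(c("GA", "GB"),
                                               c("s1", "s2", "s3"))),
                        sparse = TRUE)
  suppressWarnings(SpatialTissue(cnt, coords = cbind(c(0, 1, 2), c(0, 0, 1)),
                                 domains = c(0L, 1L, 1L)))
}
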