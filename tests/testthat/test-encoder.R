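test_that("normalization scales to the median library, log-transforms, selects HVGs", {
  # uniform libraries: scaling is a no-op before log1p
  cnt <- matrix(c(4, 0, 1, 3, 2, 2, 0, 4, 2, 1, 1, 4), nrow = 4,
                dimnames = list(sprintf("G%d", 1:4), sprintf("s%d", 1:3)))
  tis <- SpatialTissue(cnt, coords = cbind(1:3, 0))
  norm <- normalizeExpression(tis, n_hvg = 4)
  expect_true(isNormalized(norm))
  expect_equal(as.matrix(SummarizedExperiment::assay(norm, 1L)), log1p(cnt),
               tolerance = 1e-12)
  # idempotent: normalizing again returns the object unchanged
  expect_identical(normalizeExpression(norm), norm)
})

test_that("HVG selection ranks genes by dispersion and drops all-zero genes", {
  # gene A constant (dispersion ~ 0), gene B bursty (high var/mean), C all-zero
  cnt <- rbind(A = rep(5, 6), B = c(0, 0, 0, 0, 0, 30), C = rep(0, 6),
               D = c(1, 2, 1, 2, 1, 2), E = c(3, 3, 3, 3, 3, 4))
  tis <- suppressWarnings(SpatialTissue(cnt, coords = cbind(1:6, 0)))
  n1 <- suppressWarnings(normalizeExpression(tis, n_hvg = 2))
  # hand-computed dispersions rank B far first; C can never be selected
  expect_true("B" %in% rownames(n1))
  expect_false("C" %in% rownames(n1))
  expect_identical(nrow(n1), 2L)
  expect_error(normalizeExpression(tis, n_hvg = 1),
               class = "spaFuse_validation_error")
})

test_that("gcnLayer equals the brute-force triple product", {
  # identity propagation and weights pass features through
  H <- matrix(rnorm(12), 4, 3)
  I4 <- Matrix::Diagonal(4)
  expect_equal(gcnLayer(H, I4, diag(3)), H, tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero weights give activation(0) = 0 for relu/elu
  expect_equal(gcnLayer(H, I4, matrix(0, 3, 2), "relu"), matrix(0, 4, 2))
  expect_equal(gcnLayer(H, I4, matrix(0, 3, 2), "elu"), matrix(0, 4, 2))

  set.seed(31)
  for (rep in 1:5) {
    n <- sample(2:20, 1); d_in <- sample(2:20, 1); d_out <- sample(2:20, 1)
    Ahat <- normalizeAdjacency(buildAdjacency(matrix(runif(2 * n), n, 2), 0.3, 0.8))
    H <- matrix(rnorm(n * d_in), n, d_in)
    W <- matrix(rnorm(d_in * d_out), d_in, d_out)
    oracle <- matmulOracle(matmulOracle(as.matrix(Ahat), H), W)
    expect_equal(gcnLayer(H, Ahat, W, "identity"), oracle, tolerance = 1e-10)
    expect_equal(gcnLayer(H, Ahat, W, "relu"), pmax(oracle, 0), tolerance = 1e-10)
  }
  expect_error(gcnLayer(H, Ahat, matrix(0, 3, 3)),
               class = "spaFuse_validation_error")
})

test_that("the single-layer forward pass is permutation-equivariant", {
  set.seed(17)
  n <- 25
  coords <- matrix(runif(2 * n), n, 2)
  Ahat <- normalizeAdjacency(buildAdjacency(coords, 0.3, 0.7))
  H <- matrix(rnorm(n * 6), n, 6)
  W <- matrix(rnorm(6 * 4), 6, 4)
  perm <- sample(n)
  out <- gcnLayer(H, Ahat, W, "elu")
  out_p <- gcnLayer(H[perm, ], Ahat[perm, perm], W, "elu")
  expect_equal(out_p, out[perm, ], tolerance = 1e-10)
})

test_that("training is seed-deterministic, converges, and honours shapes", {
  tis <- smallTissue()
  norm <- normalizeExpression(tis)
  g <- spatialGraph(spatialCoords(norm))
  X <- as.matrix(spotExpression(norm))
  cfg <- encoderConfig(epochs = 40L, seed = 99L)
  fit1 <- trainSpatialEncoder(X, g, cfg)
  fit2 <- trainSpatialEncoder(X, g, cfg)
  expect_identical(fit1$embedding, fit2$embedding)
  expect_identical(fit1$trace, fit2$trace)
  expect_identical(ncol(fit1$embedding), 32L)
  expect_identical(length(fit1$trace), 40L)
  expect_lt(fit1$trace[40], fit1$trace[1])
  expect_true(all(is.finite(fit1$trace)))
})

test_that("k-means on the spatial embedding recovers clean synthetic domains", {
  aris <- vapply(1:5, function(s) {
    tis <- smallTissue(seed = 100 + s)
    norm <- normalizeExpression(tis)
    g <- spatialGraph(spatialCoords(norm))
    enc <- trainSpatialEncoder(as.matrix(spotExpression(norm)), g,
                               encoderConfig(epochs = 150L, seed = s))
    lab <- clusterEmbedding(standardizeStream(enc$embedding),
                            clusterConfig(n_clusters = 4L, seed = s))
    adjustedRandIndex(lab, domainTruth(tis))
  }, numeric(1))
  expect_gte(median(aris), 0.8)
})

test_that("encoder checkpoints roundtrip weights and config through text files", {
  tis <- smallTissue()
  norm <- normalizeExpression(tis)
  g <- spatialGraph(spatialCoords(norm))
  X <- as.matrix(spotExpression(norm))
  enc <- trainSpatialEncoder(X, g, encoderConfig(epochs = 10L, seed = 2))
  dir <- withr::local_tempdir()
  writeEncoderCheckpoint(enc, dir)
  back <- readEncoderCheckpoint(dir)
  expect_identical(length(back$weights), length(enc$weights))
  for (l in seq_along(enc$weights)) {
    expect_equal(back$weights[[l]], enc$weights[[l]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # restored weights re-embed the data identically
  H1 <- gcnLayer(X, g@Ahat, enc$weights[[1]], "elu")
  H2 <- gcnLayer(H1, g@Ahat, enc$weights[[2]], "identity")
  H1b <- gcnLayer(X, g@Ahat, back$weights[[1]], "elu")
  H2b <- gcnLayer(H1b, g@Ahat, back$weights[[2]], "identity")
  expect_equal(H2b, H2, tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(back$config$activation, "elu")
  expect_error(readEncoderCheckpoint(file.path(dir, "nope")),
               class = "spaFuse_io_error")
})

test_that("encoder config validation rejects impossible settings", {
  expect_error(encoderConfig(d_latent = 1), class = "spaFuse_validation_error")
  expect_error(encoderConfig(epochs = 0), class = "spaFuse_validation_error")
  expect_error(encoderConfig(learning_rate = 0), class = "spaFuse_validation_error")
})
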