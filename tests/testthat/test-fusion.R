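test_that("functional embedding is the expression-weighted gene-vector sum", {
  Fm <- rbind(c(1, 0, 1), c(0, 1, 1))
  # one-hot expression selects the gene's vector exactly
  X1 <- rbind(c(1, 0))
  expect_equal(functionalEmbed(X1, Fm), rbind(c(1, 0, 1)), ignore_attr = TRUE)
  # zero expression annihilates
  expect_equal(functionalEmbed(matrix(0, 2, 2), Fm), matrix(0, 2, 3))
  # hand matmul: X = [[1,2],[0,3]], F = I extended with a ones column
  X <- rbind(c(1, 2), c(0, 3))
  expect_equal(functionalEmbed(X, Fm), rbind(c(1, 2, 3), c(0, 3, 3)),
               ignore_attr = TRUE)
  expect_error(functionalEmbed(X, Fm[1, , drop = FALSE]),
               class = "spaFuse_validation_error")
})

test_that("functional embedding agrees with a scalar triple-loop oracle", {
  set.seed(23)
  for (rep in 1:4) {
    n <- sample(2:50, 1); m <- sample(2:50, 1); d <- sample(2:8, 1)
    X <- matrix(rpois(n * m, 2), n, m)
    Fm <- matrix(rnorm(m * d), m, d)
    expect_equal(functionalEmbed(X, Fm), matmulOracle(X, Fm), tolerance = 1e-10)
    # sparse input takes the same value
    expect_equal(functionalEmbed(Matrix::Matrix(X, sparse = TRUE), Fm),
                 matmulOracle(X, Fm), tolerance = 1e-10)
  }
})

test_that("stream standardization centers, scales by population sd, idempotent", {
  # column [1, 3]: mean 2, population sd 1 -> [-1, 1]
  H <- cbind(c(1, 3), c(5, 5))
  S <- standardizeStream(H)
  expect_equal(S[, 1], c(-1, 1))
  expect_equal(S[, 2], c(0, 0))          # constant column -> zeros
  expect_equal(standardizeStream(S), S, tolerance = 1e-10)  # idempotent
  expect_error(standardizeStream(H[1, , drop = FALSE]),
               class = "spaFuse_validation_error")
})

test_that("fusion weights combine streams as specified", {
  H1 <- matrix(rnorm(20), 5, 4)
  H2 <- matrix(rnorm(20), 5, 4)
  # alpha = 1, beta = 0 reduces to the (standardized) spatial stream
  expect_equal(fuseEmbeddings(H1, H2, fusionConfig(alpha = 1, beta = 0)),
               standardizeStream(H1), tolerance = 1e-12)
  # identical streams are a fixed point of equal weighting
  expect_equal(fuseEmbeddings(H1, H1, fusionConfig(0.5, 0.5)),
               standardizeStream(H1), tolerance = 1e-12)
  # hand arithmetic without standardization
  expect_equal(fuseEmbeddings(rbind(c(2, 0), c(2, 0)), rbind(c(0, 2), c(0, 2)),
                              fusionConfig(0.5, 0.5, standardize = FALSE)),
               rbind(c(1, 1), c(1, 1)))
  # linearity in the unstandardized convention
  a <- 3.7
  expect_equal(fuseEmbeddings(a * H1, a * H2, fusionConfig(standardize = FALSE)),
               a * fuseEmbeddings(H1, H2, fusionConfig(standardize = FALSE)),
               tolerance = 1e-12)
  expect_error(fuseEmbeddings(H1, H2[, 1:3]), "applyPCA",
               class = "spaFuse_validation_error")
  expect_error(fusionConfig(alpha = 0, beta = 0),
               class = "spaFuse_validation_error")
})

test_that("the end-to-end driver yields labels, report and reproducibility", {
  tis <- smallTissue()
  tab <- smallTable(tis)
  ecfg <- encoderConfig(epochs = 30L)
  fit <- suppressWarnings(runSpaFuse(tis, tab, encoder_config = ecfg, seed = 5))
  lab <- predictedDomains(fit)
  expect_identical(length(lab), ncol(tis))
  expect_identical(sort(unique(lab)), 0:3)
  expect_identical(dim(fusedEmbedding(fit)), c(400L, 32L))
  rep <- runReport(fit)
  expect_true(rep$ari >= -1 && rep$ari <= 1)
  expect_identical(rep$dims$fused, 32L)
  expect_gt(rep$sigma, 0)

  fit2 <- suppressWarnings(runSpaFuse(tis, tab, encoder_config = ecfg, seed = 5))
  expect_identical(fusedEmbedding(fit2), fusedEmbedding(fit))
  expect_identical(predictedDomains(fit2), lab)
})

test_that("ablation weights reproduce the single-stream pipelines exactly", {
  tis <- smallTissue()
  tab <- smallTable(tis)
  ecfg <- encoderConfig(epochs = 30L)

  expr_only <- suppressWarnings(runSpaFuse(
    tis, tab, encoder_config = ecfg,
    fusion_config = fusionConfig(alpha = 1, beta = 0), seed = 9))
  expect_identical(runReport(expr_only)$functional_stream, "disabled")

  # the expression-only pipeline: same stages without any functional fusion
  norm <- normalizeExpression(tis)
  g <- spatialGraph(spatialCoords(norm))
  enc <- trainSpatialEncoder(as.matrix(spotExpression(norm)), g,
                             encoderConfig(epochs = 30L,
                                           seed = deriveSeed(9, "encoder")))
  lab_ref <- clusterEmbedding(standardizeStream(enc$embedding),
                              clusterConfig(n_clusters = 4L,
                                            seed = deriveSeed(9, "cluster")))
  expect_identical(fusedEmbedding(expr_only), standardizeStream(enc$embedding))
  expect_identical(predictedDomains(expr_only), lab_ref)

  func_only <- suppressWarnings(runSpaFuse(
    tis, tab, encoder_config = ecfg,
    fusion_config = fusionConfig(alpha = 0, beta = 1), seed = 9))
  expect_identical(runReport(func_only)$spatial_stream, "disabled")
  aln <- alignGenes(geneSymbols(norm), tab)
  H_llm <- functionalEmbed(spotExpression(norm)[, aln$kept_gene_indices],
                           aln$F_matrix)
  H_pca <- applyPCA(fitPCA(H_llm, 32L), H_llm)
  expect_identical(fusedEmbedding(func_only), standardizeStream(H_pca))
})
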