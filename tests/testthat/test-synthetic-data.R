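test_that("the band layout partitions the lattice exactly and reproducibly", {
  tis <- makeTissue(tissueSpec())
  lab <- domainTruth(tis)
  # K divides the 40 rows: every band holds rows*cols/K spots
  expect_identical(unname(table(lab)), rep(320L, 5L), ignore_attr = TRUE)
  expect_identical(sort(unique(lab)), 0:4)
  # bands are contiguous in y
  xy <- spatialCoords(tis)
  for (k in 0:3) {
    expect_lt(max(xy[lab == k, "sdimy"]), min(xy[lab == k + 1, "sdimy"]) + 1e-9)
  }
  expect_identical(SummarizedExperiment::assay(makeTissue(tissueSpec()), 1L),
                   SummarizedExperiment::assay(tis, 1L))
  expect_false(identical(
    SummarizedExperiment::assay(makeTissue(tissueSpec(seed = 2)), 1L),
    SummarizedExperiment::assay(tis, 1L)))
})

test_that("program genes are uplifted only inside their own domain", {
  tis <- makeTissue(tissueSpec(seed = 3))
  programs <- S4Vectors::metadata(tis)$programs
  lab <- domainTruth(tis)
  X <- as.matrix(SummarizedExperiment::assay(tis, 1L))
  g0 <- which(programs == 0L)
  in_mean <- mean(X[g0, lab == 0L])
  out_mean <- mean(X[g0, lab != 0L])
  expect_gt(in_mean, 4)    # ~ baseline + signal = 5.3
  expect_lt(out_mean, 1)   # ~ baseline = 0.3
  # background genes are flat across domains
  bg <- which(is.na(programs))
  expect_lt(abs(mean(X[bg, lab == 0L]) - mean(X[bg, lab != 0L])), 0.1)
})

test_that("with no signal the expression pipeline carries no domain information", {
  tis <- smallTissue(seed = 77, signal = 0)
  norm <- normalizeExpression(tis)
  g <- spatialGraph(spatialCoords(norm))
  enc <- trainSpatialEncoder(as.matrix(spotExpression(norm)), g,
                             encoderConfig(epochs = 40L, seed = 1))
  lab <- clusterEmbedding(standardizeStream(enc$embedding),
                          clusterConfig(n_clusters = 4L, seed = 1))
  expect_lt(abs(adjustedRandIndex(lab, domainTruth(tis))), 0.15)
})

test_that("tissue spec validation enforces its invariants", {
  expect_error(tissueSpec(n_domains = 5, program_size = 50, n_genes = 100),
               class = "spaFuse_validation_error")
  expect_error(tissueSpec(baseline_rate = 0), class = "spaFuse_validation_error")
  expect_error(tissueSpec(signal = -1), class = "spaFuse_validation_error")
  # negative binomial noise is overdispersed relative to poisson
  nb <- makeTissue(tissueSpec(noise_model = "nb", nb_dispersion = 0.5, seed = 4))
  po <- makeTissue(tissueSpec(seed = 4))
  Xnb <- as.matrix(SummarizedExperiment::assay(nb, 1L))
  Xpo <- as.matrix(SummarizedExperiment::assay(po, 1L))
  expect_gt(var(as.vector(Xnb)), var(as.vector(Xpo)))
})

test_that("embedding tables are program-coherent exactly as dialled", {
  programs <- S4Vectors::metadata(makeTissue(tissueSpec(seed = 5)))$programs
  cosineMatrix <- function(E) {
    En <- E / sqrt(rowSums(E^2))
    tcrossprod(En)
  }
  within_between <- function(coh, seed) {
    tab <- makeEmbeddingTable(embeddingSpec(program_coherence = coh, seed = seed),
                              programs)
    E <- embeddingMatrix(tab)
    cs <- cosineMatrix(E)
    prog <- programs[rownames(E)]
    same <- outer(prog, prog, "==") & !is.na(outer(prog, prog, "=="))
    diag(same) <- NA
    pair_ok <- !is.na(outer(prog, prog)) # both genes in some program
    diag(pair_ok) <- FALSE
    c(within = mean(cs[same & pair_ok], na.rm = TRUE),
      between = mean(cs[!same & pair_ok], na.rm = TRUE))
  }
  wb_hi <- within_between(0.8, 21)
  expect_gt(wb_hi["within"], wb_hi["between"] + 0.3)
  wb_lo <- within_between(0.001, 21)
  expect_lt(abs(wb_lo["within"] - wb_lo["between"]), 0.1)

  tab <- makeEmbeddingTable(embeddingSpec(dim = 48, seed = 1), programs)
  expect_identical(embeddingDim(tab), 48L)
  expect_identical(embeddingMatrix(makeEmbeddingTable(embeddingSpec(seed = 9),
                                                      programs)),
                   embeddingMatrix(makeEmbeddingTable(embeddingSpec(seed = 9),
                                                      programs)))
  expect_error(embeddingSpec(program_coherence = 1),
               class = "spaFuse_validation_error")
})

test_that("the fixture suite writes twelve valid, byte-stable sections", {
  dir1 <- withr::local_tempdir()
  small <- list(grid_rows = 6L, grid_cols = 6L, n_domains = 2L,
                n_genes = 20L, program_size = 4L)
  paths <- makeFixtureSuite(dir1, seed = 2, tissue_args = small)
  expect_identical(length(paths$sections), 12L)
  expect_true(all(dir.exists(paths$sections)))
  # everything rereads and validates against the type invariants
  back <- readSpatialDataset(paths$tissue)
  expect_s4_class(back, "SpatialTissue")
  expect_true(validObject(back))
  tab <- readGeneEmbeddingTable(paths$embeddings)
  expect_identical(nrow(embeddingMatrix(tab)), 20L)
  sec1 <- readSpatialDataset(paths$sections[1])
  expect_identical(length(unique(domainTruth(sec1))), 2L)

  # same seed -> byte-identical files
  dir2 <- withr::local_tempdir()
  makeFixtureSuite(dir2, seed = 2, tissue_args = small)
  for (f in c("gene_embeddings.csv", "tissue/matrix.mtx", "tissue/coords.tsv",
              "sections/section_07/matrix.mtx")) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
})
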