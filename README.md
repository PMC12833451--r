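# spaFuse

Spatial domain identification for spatial transcriptomics by fusing two
complementary spot representations:

1. a **spatial stream** — embeddings from a graph-convolutional autoencoder
   trained on the normalized expression matrix over a Gaussian-kernel
   spatial proximity graph, and
2. a **functional stream** — embeddings obtained by multiplying the
   expression matrix with a precomputed table of per-gene text-description
   embedding vectors (e.g. vectors encoding NCBI gene summaries), so each
   spot is represented by the expression-weighted sum of its genes'
   functional vectors.

The package is for analysts of sequencing-based (Visium-style) or
imaging-based spatial data who want domain calls that remain informative
when expression data is sparse or degraded, and for method developers who
need a reproducible, fully offline benchmark of that claim.

## The model

Given expression `X` (n spots × m genes), coordinates `C` (n × 2) and a
gene-embedding table `F` (m' × d_llm):

- spatial graph: `A_ij = exp(-||c_i - c_j||² / (2σ²))` for distances ≤ τ,
  else 0; normalized `Â = D̃^{-1/2}(A + I)D̃^{-1/2}`;
- spatial stream: graph-convolutional autoencoder with layer update
  `H⁽ˡ⁺¹⁾ = act(Â H⁽ˡ⁾ W⁽ˡ⁾)`, trained to reconstruct the normalized
  expression; the latent output is `H_ST` (n × d);
- functional stream: `H_fn = X F`, reduced to width d by PCA;
- fusion: `Z = α·H_ST + β·H_fn^PCA` (streams standardized first; defaults
  α = β = 0.5), then clustering (k-means / Louvain / Gaussian mixture);
- evaluation: adjusted Rand index (ARI) against manual annotations —
  1 for identical partitions, ≈ 0 at chance.

A quality-degradation simulator zeroes 50 / 75 / 87.5 / 93.75 % of the
non-zero entries (levels Q1–Q4), and a benchmark harness scores the fusion
strategies (expression-only, functional-only, concatenation, weighted)
across the grid. A synthetic-tissue generator with program-correlated
embedding tables makes the whole system testable without downloads.

## Worked example

```r
library(spaFuse)

# a 40x40 lattice, 5 banded domains, 200 genes (20 markers per domain),
# plus an embedding table whose vectors are correlated within programs
tissue <- makeTissue(tissueSpec(seed = 11))
table  <- makeEmbeddingTable(embeddingSpec(seed = 12),
                             S4Vectors::metadata(tissue)$programs)

fit <- runSpaFuse(tissue, table, seed = 5)
rep <- runReport(fit)
rep$sigma; rep$tau
#> [1] 0.7727569
#> [1] 1.545514
rep$ari
#> [1] 1
table(predictedDomains(fit), domainTruth(fit))
```

`runSpaFuse()` returns the tissue with the spatial, functional and fused
embeddings in `reducedDims()`, predictions in `colData()$domain_pred`, and a
report (graph parameters, dropped genes, seeds, per-stage dimensions, ARI
when truth is present) in `metadata()$spaFuse`. Here the derived kernel
cutoff τ ≈ 1.55 lattice units encloses the 8-neighborhood of the unit grid
and the fused clustering reproduces the generating bands exactly (ARI 1.0).

Degradation benchmark (2 runs per cell shown; `n_runs = 10` is the default):

```r
bench <- benchmarkQuality(tissue, table, n_runs = 2, seed = 3)
cat(formatBenchmarkTable(bench), sep = "\n")
#> strategy           Q0           Q1           Q2           Q3           Q4
#> expression_only    1.000±0.000 1.000±0.000 1.000±0.000 0.974±0.003 0.710±0.075
#> functional_only    1.000±0.000 1.000±0.000 0.946±0.000 0.716±0.000 0.394±0.002
#> concatenation      1.000±0.000 1.000±0.000 0.999±0.001 0.968±0.005 0.649±0.065
#> weighted           0.998±0.002 0.993±0.001 0.967±0.007 0.858±0.041 0.518±0.115
```

Every strategy degrades as masking deepens; on this strongly-marked
synthetic tissue the spatially smoothed expression stream is the most
mask-robust (see the methods vignette for why, and for how this differs
from sparse real tissue).

A command-line wrapper is installed at `inst/scripts/spafuse`:

```sh
Rscript inst/scripts/spafuse synth --preset default --out data --seed 7
Rscript inst/scripts/spafuse run --data data/tissue \
    --embeddings data/gene_embeddings.csv --out results --seed 7
Rscript inst/scripts/spafuse eval --pred results/labels.csv --truth truth.csv
```

## Layout

- `R/` — S4 classes (`SpatialTissue`, `GeneEmbeddingTable`, `SpatialGraph`,
  `PCAModel`) and the pipeline stages, one file per stage.
- `tests/testthat/` — module tests with independent brute-force oracles,
  plus the acceptance suite.
- `vignettes/spatial-domain-fusion.Rmd` — the methods vignette: model,
  assumptions, parameter meanings, numerical choices, limitations.
- `scripts/acceptance.R` — see above.
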