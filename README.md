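# stabica

Stabilized independent component analysis (ICA) of gene-expression
matrices, with a data-driven choice of the number of components and
machinery for comparing components within and across datasets.

## The problem

ICA decomposes a log-scale expression matrix as **X ≈ AS**: the rows of
**S** are *metagenes* (gene-weight vectors of latent transcriptional
programs, heavy-tailed by the biology of co-regulated modules) and the
columns of **A** are the corresponding sample loadings. Two issues stand
between the model and reliable biology:

* fastICA is a non-convex optimization from a random start — different
  runs can return different components;
* the decomposition order *M* must be chosen — too small fuses distinct
  programs, too large splits them and floods the result with unstable,
  often single-gene-driven components.

`stabica` implements the stabilization protocol and its companion order
criterion:

1. **Stabilized decomposition** (`decompose_stabilized`): *K* fastICA runs
   (pow3 contrast, symmetric decorrelation) from seeded random starts; the
   pooled *K·M* components are clustered (dissimilarity 1 − |r|) and each
   cluster is scored with the stability index
   *I_q* = (average within-cluster |r|) − (average between-cluster |r|),
   represented by its centrotype, oriented so its heavy tail is positive,
   and ranked by stability.
2. **MSTD** (`scan_orders` + `estimate_mstd`): scanning *M* over a grid and
   overlaying all stability profiles as (rank, *I_q*) points exposes a
   high-stability region and a low-stability mode; two lines fitted by
   k-lines clustering intersect at the **Maximally Stable Transcriptome
   Dimension** — the largest order before over-decomposition takes over.
   Kaiser and broken-stick baselines come from `baseline_dimensions`.
3. **Comparison** (`match_sets`, `build_match_graph`,
   `reproducibility_scores`, `classify_conservation`,
   `detect_small_geneset`, `hypergeom_enrich`, `jaccard_top_genes`):
   best-matched / reciprocal correlation matching of metagenes, reciprocal
   correlation graphs across cohorts (edges |r| > 0.3), reproducibility
   scores (sum of reciprocal correlations, bounded by the number of other
   datasets), conservation classes (conserved / split / not conserved)
   across orders, and annotation of components by their top-contributing
   genes (weight > 5.0).

A synthetic-data module (`generate_factor_data`,
`generate_perfect_clusters`, `generate_two_line_points`,
`generate_two_regime_scan`) plants known ground truth for every claim the
package makes.

## Worked example

```r
library(stabica)

sim  <- generate_factor_data(generator_config(
  n_genes = 2000, n_samples = 200, k_sources = 10, seed = 11))
dec  <- decompose_stabilized(sim$X, M = 10, K = 20, seed = 5)
dec
#> <ica_decomposition> M = 10 (20 runs), 2000 genes x 200 samples
#>   stability: 1.000 (top) .. 1.000 (bottom), mean 1.000
#>   explained variance fraction: 0.990

match_sets(sim$metagenes_true, dec)   # planted-source recovery
#> # A tibble: 10 × 6
#>   query    match      r abs_r   gap reciprocal
#>   <chr>    <chr>  <dbl> <dbl> <dbl> <lgl>
#> 1 source_1 IC5   -1.000 1.000  848. TRUE
#> 2 source_2 IC2   -1.000 1.000 1019. TRUE
#> 3 source_3 IC10   1.000 1.000 1014. TRUE
#> # … all ten planted metagenes matched with |r| > 0.999, all reciprocal

scan <- scan_orders(sim$X, grid = 2:30, K = 20, seed = 121)
estimate_mstd(scan)
#> <mstd_result> MSTD = 11 (two_line_intersection)
#>   line intersection at rank 10.51; nearest scanned order 11
```

The decomposition recovers all ten planted programs essentially exactly
(stability ≈ 1 at the true order), and the order scan places the MSTD at
11 for a planted dimension of 10 — the criterion flags the last order
before components stop being reproducible across runs, which on this data
sits just above the planted rank. `autoplot(scan)` and
`autoplot(estimate_mstd(scan))` draw the stability-profile cloud with the
fitted lines and MSTD marker; `tidy()`/`glance()` methods return tibbles
for every result type.

A command-line layer wraps the same functions
(`exec/stabica simulate|decompose|scan|mstd|compare|conserve|annotate`),
writing JSON provenance sidecars and cached per-order decompositions.

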