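Package: stabica
Title: Stabilized Independent Component Analysis of Transcriptomes and
    the Maximally Stable Transcriptome Dimension
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Multi-run ('icasso'-style) independent component analysis of
    log-scale gene expression matrices with stability-based component
    ranking, estimation of the Maximally Stable Transcriptome Dimension
    (MSTD) by two-line clustering of overlaid stability profiles, and
    machinery for comparing metagenes within and across datasets:
    reciprocal-correlation match graphs, reproducibility scores,
    conservation of components across decomposition orders, detection of
    components driven by small gene sets, and gene-set enrichment of
    component loadings. Includes a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ica,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
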