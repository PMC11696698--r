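Package: spotdecon
Title: Reference-Based Cell-Type Deconvolution for Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-spot cell-type proportions in sequencing-based
    spatial transcriptomics data from a labelled single-cell RNA-seq
    reference. Models each spot's expression as a non-negative weighted sum
    of reference cell profiles ("prototypes") and provides two estimators:
    ridge-regularized non-negative least squares solved by projected
    gradient descent, and a fast soft-thresholded ordinary least squares
    variant. Includes gene-split cross-validation for the ridge penalty,
    reference preprocessing (per-cell normalization, rare-type filtering,
    one-vs-rest Wilcoxon marker selection), evaluation metrics (RMSE,
    Jensen-Shannon divergence, marker-gene Pearson correlation), a
    synthetic mixture generator with known ground truth, and spatial
    scatter-pie and per-type proportion plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    scales,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
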