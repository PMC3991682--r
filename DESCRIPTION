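Package: icnoise
Title: Automated Classification of Noise Components in fMRI ICA Decompositions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Distinguishes noise from functional-network components in
    resting-state fMRI independent component analysis (ICA) decompositions.
    Reads MELODIC-style output (4D component Z-maps plus a mixing matrix),
    extracts an ordered catalogue of spatial descriptors (atlas region voxel
    counts, tissue/region activation percentages, distribution moments and
    entropy, local-maxima cluster metrics, left-right mirror symmetry) and
    temporal descriptors (moments, spectral band powers, high-frequency
    fraction, extrema and jump statistics, autocorrelations, dynamic spectral
    range/count metrics), and fits a sparse classifier: an elastic-net
    feature-selection stage solved by cyclic coordinate descent with a
    10-fold cross-validated grid search over the mixing parameter and penalty
    strength, followed by a logistic refit on the selected features and
    ROC-based operating-threshold selection with binomial confidence
    intervals. A synthetic phantom generator produces labelled toy
    decompositions so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
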