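Package: sersdx
Title: Chemometric Discrimination of Two-Group SERS Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for surface-enhanced Raman
    spectroscopy (SERS) liquid-biopsy diagnostics. Provides spectrum and
    cohort I/O for two-column wavenumber/intensity files, a synthetic
    SERS cohort generator with configurable vibrational-band effect
    directions, spectral preprocessing (modified z-score despiking,
    asymmetric least squares baseline removal, replicate averaging,
    uniform resampling by linear interpolation, standard normal variate
    normalization), per-wavenumber Welch tests with Benjamini-Hochberg
    false discovery rate control, PCA-LDA classification under
    leave-one-out cross-validation, and confusion-matrix/ROC diagnostic
    reports over full-range and restricted spectral windows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
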