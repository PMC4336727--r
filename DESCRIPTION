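Package: anthesis
Title: Detecting and Quantifying Rice Panicle Flowering in Canopy Time-Lapse Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the flowering (anthesis) parts of rice panicles in RGB
    canopy images and quantifies daily and diurnal flowering dynamics from
    time-lapse sequences. Images are scanned with non-overlapping sliding
    windows; each window is described by a bag-of-visual-words histogram over
    dense multi-scale SIFT descriptors, classified by a linear support vector
    machine on a homogeneous-kernel-map approximation of the chi-square
    kernel, and positive windows are merged into connected flowering regions.
    Includes a seeded synthetic canopy generator with ground truth, so the
    whole pipeline is testable without field imagery, plus protocol helpers
    for training-set-size and image-resolution experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    e1071,
    stats,
    utils,
    png,
    EBImage,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
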