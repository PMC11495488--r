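Package: trabkit
Title: Trabecular Bone Morphometry and Ontogenetic Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies trabecular bone architecture in articular heads from
    micro-CT image stacks and analyses the resulting metrics across an
    ontogenetic cohort. Provides synthetic rod-lattice phantoms and whole-bone
    mocks with known ground truth, standardized bone orientation and
    left-element mirroring, spherical region-of-interest extraction with Otsu
    binarization and purification, mean-intercept-length fabric tensors with
    degree of anisotropy and principal orientation (azimuth/plunge), local
    thickness and spacing, trabecular number, and a cohort statistics stage:
    coefficients of variation, Pearson and partial correlations, principal
    component analysis, Kruskal-Wallis and Dunn tests, allometric log-log
    regressions with isometry comparison and k-fold polynomial degree
    selection, and lower-hemisphere equal-area orientation projections.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
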