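Package: cfadetect
Title: Cellular Frustration Algorithms for Semi-Supervised Anomaly Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Immune-inspired anomaly detection built on cellular frustration:
    a population of presenter and detector agents engages in stable-marriage
    style pairing dynamics whose pairing lifetimes destabilise when a sample
    unlike the training data is displayed. Provides the frustrated pairing
    dynamics, repertoire education by negative selection (full-list
    replacement) or targeted rank swaps, anergy-based monitoring with
    calibrated activation thresholds, absorbing Markov chain theory for the
    convergence of the two education strategies, rule-based counting
    baselines, semi-supervised dataset splitting in the Monte-Carlo
    cross-validation style, and a synthetic data generator covering three
    anomaly mechanisms (out-of-range outliers, excess absence of frequent
    signals, broken signal co-occurrence).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
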