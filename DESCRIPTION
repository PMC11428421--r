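Package: navreg
Title: Surface Registration with Learned Refinement for Surgical Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Rigid surface registration toolkit for image-guided surgery
    point clouds. Implements SVD-based paired-point coarse registration from
    anatomical landmarks, a point-cloud regression network that predicts a
    corrective rigid transform from coarse-registered landmarks (trained on
    automatically simulated landmark-localization errors), and point-to-point
    iterative closest point (ICP) fine registration. Ships a synthetic
    head-phantom generator with internal target grids and restricted surface
    acquisition patterns, and an evaluation harness reporting surface
    registration error (SRE) and depth-stratified target registration error
    (TRE).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
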