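Package: longconn
Title: Longitudinal Weighted Brain Connectome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal analysis of weighted functional and
    structural brain connectivity networks in a two-group, repeated-measures
    design. Implements weighted graph topology metrics with harmonic-mean
    (disconnection-safe) path lengths, proportional density thresholding,
    small-world indices against degree-preserving null ensembles,
    functional-structural connectivity coupling via rank-based Gaussian
    resampling, mixed-design repeated-measures ANOVA with a per-node
    false-positive adjustment, change-score correlations, split-half
    reproducibility with covariate-matched subgroups, and a synthetic
    longitudinal connectome generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
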