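Package: penfeed
Title: Random-Regression Genetic Evaluation of Group- and Individual-Level
    Feed Intake
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for joint genetic analysis of feed intake recorded at the
    group level (pigs sharing a feeder) and at the individual level (test
    station), using bivariate random-regression test-day models on Legendre
    polynomial bases. Provides a pedigree-and-genotype simulator with
    weight-sorted pens and pooled group records, pedigree (A), genomic (G)
    and combined single-step (H) relationship matrices, average-information
    REML estimation of covariance functions with heterogeneous residual
    classes, PBLUP/ssGBLUP prediction via Henderson's mixed-model equations,
    per-day heritability and genetic-correlation trajectories, and
    leave-one-group-out cross-validation with partial/whole comparison
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
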