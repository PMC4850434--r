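Package: mmtsa
Title: Genotype Meta-Analysis, Trial Sequential Analysis and Mendelian
    Randomization for Plasma Homocysteine and Multiple Myeloma
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates the association between the MTHFR C677T polymorphism
    and multiple myeloma risk from per-study case-control genotype counts,
    and translates it into a causal effect of plasma homocysteine via a
    single-instrument Wald ratio. Implements Hardy-Weinberg testing, five
    genetic-model contrasts, Mantel-Haenszel fixed-effect and
    DerSimonian-Laird random-effects pooling with heterogeneity statistics,
    leave-one-out sensitivity analysis, Egger and Begg publication-bias
    diagnostics, diversity-adjusted trial sequential analysis with
    O'Brien-Fleming alpha-spending monitoring boundaries, analytic power for
    Mendelian randomization with a binary outcome, and a calibrated
    synthetic-data generator so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
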