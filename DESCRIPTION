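Package: adrscreen
Title: Mixed-Model Disproportionality Screening for Spontaneous
    Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Signal detection for spontaneous adverse-event reporting
    databases. Estimates the proportional reporting ratio (PRR) and the
    reporting odds ratio (ROR) for every adverse drug reaction of a target
    drug in a single generalized linear mixed-model fit (Poisson or
    logistic, estimated by restricted pseudo-likelihood), with BLUP-based
    95 percent prediction intervals and the conventional lower-limit
    signal rule.  Extends to drug-drug interaction screening through
    interaction terms, provides the classical per-reaction PRR/ROR with
    Wald intervals as a comparator, and ships a reproducible simulation
    harness for false-positive-rate and sensitivity experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
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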