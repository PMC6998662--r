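Package: serotraj
Title: Prediagnostic Serum RNA Signal Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for circulating RNA dynamics in prediagnostic
    serum cohorts. Provides a synthetic cohort generator with negative-binomial
    counts, covariate confounding and time-to-diagnosis-dependent effects;
    frequency and optimal case-control matching; fixed and sliding
    prediagnostic time windows with stage-balanced sample selection;
    covariate-adjusted negative-binomial Wald differential expression with
    Benjamini-Hochberg correction; bootstrap robustness summaries, RNA-class
    signal trajectories and peak detection; and hypergeometric pathway
    over-representation for mRNAs and predicted miRNA/isomiR targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
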