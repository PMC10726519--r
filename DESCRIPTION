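Package: ps4calib
Title: Quantitative Calibration of the ACMG/AMP PS4 Case-Control Enrichment Criterion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives evidence-strength thresholds (supporting, moderate, strong)
    for the ACMG/AMP PS4 criterion from labelled case-control variant tables.
    Implements Bayesian evidence-strength calibration (combined odds of
    pathogenicity, posterior probabilities, likelihood-ratio thresholds),
    exact per-variant association statistics (Fisher exact p, conditional
    maximum-likelihood odds ratios with exact confidence intervals),
    odds-ratio and allele-count cutoff scans with bootstrap confidence
    intervals for the positive likelihood ratio, sliding-window local
    positive-likelihood-ratio estimation, an ACMG/AMP evidence-combination
    engine with ACGS VUS temperature grading, and a synthetic case-control
    cohort generator for end-to-end testing.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
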