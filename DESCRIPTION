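Package: lateralize
Title: Laterality Analysis for Repeated Binary Side-Preference Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies motor laterality from repeated binary side
    observations, as in studies of gallop leading-leg preference in
    racehorses. Provides the laterality index, per-individual one-proportion
    tests (normal approximation and exact binomial with tail doubling) with
    significance classification, population-level proportion and
    logistic-regression association tests, a two-normal-mixture bimodality
    criterion with a separation-factor table, variance-pretested pooled and
    Welch two-sample comparisons of laterality strength, Anderson-Darling
    normality testing with a Johnson transformation, power and sample-size
    design for one proportion, Cronbach's alpha for inter-observer
    reliability, and a synthetic cohort simulator for operating-characteristic
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
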