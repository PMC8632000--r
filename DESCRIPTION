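Package: vancopk
Title: Population Pharmacokinetics and Renal Dose Tailoring of Vancomycin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Nonlinear mixed-effects analysis of vancomycin plasma
    concentration data from sparse therapeutic-drug-monitoring designs.
    Provides closed-form one- and two-compartment intravenous-infusion
    models, first-order conditional estimation with interaction (FOCE-I)
    with empirical Bayes estimates and conditional weighted residuals,
    stepwise covariate modeling with likelihood-ratio thresholds,
    nonparametric bootstrap and visual predictive checks, Monte-Carlo
    steady-state trough simulation with dose tailoring against a target
    trough range, and a synthetic-cohort generator emulating an adult
    surgical population so the whole pipeline is testable without
    patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
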