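Package: fupk
Title: Population Pharmacokinetics of Fluorouracil and Skeletal Muscle Index
    Effects on Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fluorouracil (5FU) therapeutic drug monitoring
    data together with CT-derived skeletal muscle indices (SMI). Implements a
    one-compartment continuous-infusion population pharmacokinetic model with
    centered covariate effects on clearance, a Laplace-type (FOCE with
    interaction) marginal-likelihood estimator with empirical Bayes estimates
    and shrinkage, likelihood-ratio based stepwise covariate modeling, a
    non-parametric subject-level bootstrap, prediction-corrected visual
    predictive checks, and logistic-regression analysis of severe
    (CTCAE grade >= 2) adverse-event probability as a function of SMI.
    Includes a synthetic-cohort generator emulating a therapeutic drug
    monitoring population so the full pipeline is testable without patient
    data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
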