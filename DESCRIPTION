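Package: bdqpk
Title: Population Pharmacokinetics of Bedaquiline with Hepatic and
    Pharmacogenetic Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical one-compartment population-pharmacokinetic modelling
    of bedaquiline in adults treated for multidrug-resistant tuberculosis.
    Provides closed-form first-order-absorption kinetics at steady state, a
    covariate model linking apparent clearance to gamma-glutamyl transferase
    (power model) and the AGBL4 rs319952 genotype (additive shift), a
    FOCE-with-interaction (Laplacian) nonlinear mixed-effects estimation
    engine with empirical Bayes estimates, shrinkage and conditional weighted
    residuals, stepwise covariate modelling with likelihood-ratio forward
    inclusion and backward elimination, nonparametric subject-level bootstrap,
    prediction-corrected visual predictive checks, steady-state dosage
    simulation across covariate strata, and a synthetic-data generator that
    emulates the sparse thrice-weekly sampling design of the study.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
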