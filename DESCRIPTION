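Package: neocef
Title: Population Pharmacokinetics and Dose Optimization of Ceftazidime
    in Neonates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonlinear mixed-effects analysis of sparse neonatal
    ceftazidime concentration data from dried-blood-spot micro-sampling.
    Implements a one-compartment intravenous-infusion model with
    allometric body-weight scaling and sigmoidal postmenstrual-age
    maturation of clearance, first-order conditional (FOCE) estimation
    with empirical Bayes random effects, stepwise covariate screening,
    goodness-of-fit and visual-predictive-check diagnostics, a
    nonparametric subject-level bootstrap, and Monte Carlo probability of
    target attainment (PTA) simulation of %fT>MIC for candidate dosing
    regimens in virtual neonatal cohorts. A synthetic-study generator
    reproduces the sparse sampling design so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
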