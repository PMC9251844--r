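Package: lemcycle
Title: Density-Dependent Summer Demography of Cyclic Small-Mammal Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the summer demographic analysis of cyclic small-mammal
    (lemming) populations monitored by live-trapping on fixed grids. Implements
    spatially explicit capture-recapture (SECR) density estimation with a
    half-normal detection function and conditional likelihood, capture-history
    bootstrap estimation of sex/age composition, Huber M-estimator robust
    regression with a two-axis (errors-in-both-variables) propagation bootstrap,
    Cormack-Jolly-Seber apparent survival with unequal sampling intervals and
    AICc model selection, and negative-binomial movement, binomial reproduction
    and linear body-mass mixed models. A synthetic cyclic-population simulator
    with known truth supports parameter-recovery validation of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    Rcpp,
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
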