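Package: mmndcm
Title: Dynamic Causal Modelling of Mismatch Responses with a Canonical
    Microcircuit Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and Bayesian inversion of a canonical-microcircuit
    neural-mass model of auditory evoked fields. Provides a five-source
    auditory network (bilateral A1 and STG plus right frontal operculum),
    a melodic-oddball paradigm generator with pitch deviants, a
    single-sphere magnetometer forward model, variational-Laplace model
    inversion of condition-specific connectivity modulations, and
    group-level parametric empirical Bayes with Bayesian model reduction,
    model averaging and family inference. Synthetic cohorts with known
    ground truth support end-to-end parameter- and family-recovery
    studies of mismatch-negativity (MMN) generation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    signal,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
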