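Package: snpet
Title: Simulation-Based Inference for Mechanistic Neuroscience Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-free Bayesian inference for mechanistic models of
    neural dynamics via sequential neural posterior estimation (SNPE).
    Provides conditional density estimators (mixture density networks and
    masked autoregressive flows) trained on simulator output, single- and
    multi-round inference with importance-weighted losses, mechanistic
    simulators (linear-nonlinear encoding models, a non-inactivating
    potassium-channel kinetics family under voltage clamp, stochastic
    single-compartment Hodgkin-Huxley neurons, and a three-neuron model of
    the crustacean pyloric circuit) with their summary-feature extractors,
    classical approximate Bayesian computation and MCMC baselines, and
    posterior-geometry tools (conditional correlations, high-probability
    paths, orthogonal perturbations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    arrow,
    jsonlite,
    optparse
Config/testthat/edition: 3
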