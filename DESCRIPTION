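Package: sptstates
Title: Nonparametric Bayesian Diffusive-State Analysis for Single-Particle Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the number of diffusive states, per-axis apparent diffusion
    coefficients, state weights, transition probabilities and per-step state
    labels from two-dimensional single-particle-tracking trajectories, using a
    sticky hierarchical Dirichlet process hidden Markov model (HDP-HMM) with
    multivariate Gaussian emissions sampled by a truncated blocked Gibbs
    sampler. Includes simulators for heterogeneous Brownian motion (with
    optional motion blur and localization error), fractional Brownian motion,
    continuous-time random walks and Levy walks, and a trainable two-layer
    LSTM network that classifies the diffusion type (and regresses the
    anomalous exponent) of same-state trajectory segments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
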