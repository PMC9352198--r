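Package: rewardtaxis
Title: Dopamine Fold-Change Detection and Reward-Taxis Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic modelling of midbrain dopamine dynamics as a
    fold-change detection (FCD) circuit driven by the logarithm of expected
    reward, and of the behaviour that emerges when circuit output modulates
    locomotion. Provides ODE simulators for the integral-feedback,
    feed-forward, quasi-static and rectified circuit variants with exact
    adaptation and scale-invariance analytics; constructors for
    expected-reward signals and spatial reward fields; a run-and-tumble
    agent simulator in which dopamine modulates movement speed or tumble
    rate; the coarse-grained Langevin (Keller-Segel type) approximation with
    mechanistic diffusion and drift coefficients and its stationary law
    P(x) proportional to R(x)^beta; an operant-matching experiment harness
    that estimates the sensitivity exponent beta and bias k of the
    generalized matching law; a tabular temporal-difference learner for
    logarithmic value functions; and a nonlinear least-squares fitter for
    logarithmic dose-response curves of dopaminergic reward responses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
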