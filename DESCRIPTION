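Package: jointmsm
Title: Clustered Mover-Stayer Multistate Models for Joint Activity and Damage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits clustered continuous-time multistate models to intermittently
    observed (panel) data on paired hand joints, as arise in psoriatic arthritis
    clinics. Provides a six-state transition-intensity model and a five-state
    mean-sojourn-time / jump-probability reparameterization for the joint
    activity and damage processes, with a latent mover-stayer mixture,
    observation-level (or patient-level) bivariate normal random effects
    integrated by Gauss-Hermite quadrature, and dynamic covariates (adjusted
    mean activity, attained damaged-joint count, contralateral damage).
    Includes maximum-likelihood estimation with numerical-Hessian standard
    errors, profile likelihood for the stayer proportion, a synthetic cohort
    simulator for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    pracma,
    optparse,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
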