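Package: stableasr
Title: Ancestral State Reconstruction Under Heavy-Tailed Stable Trait Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian ancestral state reconstruction of continuous traits on
    time-calibrated phylogenies under a symmetric alpha-stable model of trait
    increments, with Brownian motion recovered as the alpha = 2 special case.
    Provides density and likelihood machinery for stable increments, a
    Metropolis-within-Gibbs sampler over stability index, dispersion and node
    states, Gelman-Rubin convergence diagnostics, BPIC model comparison against
    Brownian motion, per-branch rate multipliers relative to the input
    chronogram, fossil-tip pruning experiments, pseudo-outgroup root priors,
    and birth-death simulators for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
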