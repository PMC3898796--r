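Package: cogtomo
Title: Cognitive Tomography: Recovering Subjective Priors from Discrete Choices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cognitive tomography: inverting task-specific Bayesian
    ideal observer models to reconstruct a subject's prior ("subjective
    distribution") over a two-dimensional stimulus feature space from
    sequences of discrete choices in familiarity (two-alternative) and
    odd-one-out (three-alternative) tasks. Provides Gaussian-mixture
    representations of subjective distributions, analytic ideal observer
    likelihoods with perceptual noise integrated out, Metropolis-within-Gibbs
    posterior sampling over mixture and observer parameters, response
    prediction within and across tasks, consistency scores and the derived
    performance upper bound, Jensen-Shannon divergence comparisons with
    classical multidimensional scaling embeddings, moment-matched Gaussian
    and Gaussian-process-classifier baselines, and a synthetic-observer
    simulator for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    kernlab,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    pracma,
    mvtnorm,
    withr,
    optparse
Config/testthat/edition: 3
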