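Package: ouregime
Title: Ornstein-Uhlenbeck Adaptation Models with Regimes Painted on Phylogenies
Version: 0.1.0
Authors@R: person("ouregime", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits Ornstein-Uhlenbeck and Brownian-trend models of continuous
    trait evolution in which the trait tracks optima (or drifts at rates)
    determined by discrete selective regimes painted on a phylogeny and by
    Brownian continuous predictors, with an immediate allometric (direct)
    effect of a covariate such as body mass and observation error in species
    means. Inference is by generalized least squares conditional on the
    phylogenetic half-life and stationary variance, maximized over a grid with
    2-log-likelihood-unit support sets, and candidate predictor combinations
    are ranked by AICc. Discrete regime histories are reconstructed with Mk
    models (equal, symmetric, or all-rates-different transition matrices
    chosen by AICc), marginal ancestral states, and stochastic character
    mapping. A synthetic-data generator simulates the full system (tree,
    regime histories, Brownian predictors, OU or trend response, species-mean
    observation error) for testing and Monte-Carlo validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
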