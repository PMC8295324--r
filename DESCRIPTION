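Package: proslearn
Title: Computational Modelling of Self-Relevant and Prosocial Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com", role = c("aut", "cre"))
Description: Simulation and hierarchical model fitting for a probabilistic
    reward-learning task in which choices earn outcomes for oneself, for
    another person, or for no one. Provides a generative task simulator
    (three recipient conditions, three blocks of sixteen trials each,
    75/25 reward contingencies), a family of four Rescorla-Wagner/softmax
    models differing in how learning rates and temperatures are shared
    across recipients, iterative maximum a posteriori fitting with
    empirical group-level Gaussian priors, Laplace model evidence,
    integrated BIC and random-effects Bayesian model selection with
    exceedance probabilities, plus the simulation studies used to
    establish model identifiability, parameter recovery and the optimal
    learning rate, and the nonparametric statistical helpers used for
    group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
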