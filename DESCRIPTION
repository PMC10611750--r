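Package: volbandit
Title: Hidden Markov and Reinforcement Learning Models of Probabilistic
    Reversal Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of a composite-stimulus
    three-armed bandit with hidden reversals. Provides generative task
    simulators (signalled and reversal variants), a family of
    Rescorla-Wagner reinforcement-learning agents (with forgetting and
    confidence meta-learning), a three-parameter hidden Markov observer
    with probability-matching choice, maximum-a-posteriori fitting with
    Laplace model evidence, empirical-Bayes random-effects model
    comparison (model frequencies and exceedance probabilities),
    parameter-recoverability pipelines, behavioural dependent variables
    (learning slopes, probabilistic-error proportions), and trait-level
    statistics (Holm correction, bootstrap causal mediation, two-way
    random-effects intraclass correlation) exercised end-to-end on a
    synthetic cohort with a planted anxiety-volatility-learning structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
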