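Package: aversivetwostep
Title: Model-Free and Model-Based Aversive Learning for Self and Other
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a two-stage ("two-step")
    aversive learning task in which decisions determine painful outcomes for
    oneself or another person. Provides a generative task environment with
    drifting shock probabilities, a family of hybrid model-free/model-based
    reinforcement-learning agents with a recipient-specific model-based
    weight, hierarchical maximum a posteriori fitting via
    expectation-maximization, integrated-BIC model comparison with
    random-effects exceedance probabilities, per-subject stay/switch
    logistic regressions with default-prior (JZS) Bayes factors, and
    synthetic-cohort generators for parameter-recovery and
    incentive-equivalence control simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
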