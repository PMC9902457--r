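Package: hedoseek
Title: Hierarchical Bayesian Models of Hedonically Biased Information Seeking
Version: 0.1.0
Authors@R:
    person("Matthew", "Hargreaves", email = "m.hargreaves.dev@gmail.com",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for lottery-prediction experiments
    in which participants select between information sources ("psychics") that
    differ in the accuracy and the positivity of their example predictions, or
    rate their beliefs after a single source's prediction. Provides the trial
    design combinatorics of feasible accuracy-by-positivity source profiles,
    softmax choice models and Gaussian belief-update models with hierarchical
    (partial-pooling) priors, Hamiltonian Monte Carlo posterior inference with
    convergence diagnostics, participant-wise cross-validated model comparison
    (elpd via exact refitting or truncated importance sampling, WAIC, Bayesian
    stacking, best-predictor proportions), posterior predictive checks,
    parameter- and model-recovery studies, ROPE/HDI decision rules, and a
    synthetic cohort generator with a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
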