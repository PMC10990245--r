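Package: volbandit
Title: Environment-Specific Learning Rates in Volatility-Structured Bandit Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian analysis of two-armed bandit
    tasks in which participants alternate trial-by-trial between a stable and a
    volatile casino. Provides the task generator (balanced casino alternation,
    anticorrelated probabilistic rewards, reversal schedules), six
    Rescorla-Wagner model variants (single, dual and variable learning rates,
    each shared or environment-specific), hierarchical Bayesian estimation with
    a non-centred probit parameterisation and adaptive Markov chain Monte Carlo,
    model comparison by Pareto-smoothed importance-sampling leave-one-out
    cross-validation (LOOIC), and the accompanying simulation studies: reward
    rate parameter grids, model recovery, parameter recovery, and posterior
    predictive checks, plus model-free behavioral statistics (chance-level
    exclusion, lose-switch rates, post-reversal choice accuracy).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    coda
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
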