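Package: rsrl
Title: Risk-Sensitive Reinforcement Learning Analysis of a Probabilistic
    Reward Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Constructs the counterbalanced four-cue probabilistic reward
    task schedule, simulates choice behavior under an asymmetric
    (risk-sensitive) temporal-difference learning rule and three comparison
    models (classical delta rule, nonlinear utility, win-stay-lose-shift),
    fits model parameters per session by multi-restart maximum likelihood,
    compares nested models with likelihood-ratio tests, and summarizes
    risky-choice behavior and nonparametric group statistics for simulated
    or ingested session logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
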