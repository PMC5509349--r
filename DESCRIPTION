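Package: metaplastr
Title: Metaplastic Synapse Models for Adaptive Reward Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how synaptic metaplasticity mitigates the
    tradeoff between adaptability and precision during reward-probability
    estimation. Provides constructors for families of binary-efficacy
    metaplastic models (general symmetric, one-parameter ladder, cascade,
    reward-dependent metaplasticity, graded-efficacy), a mean-field analysis
    of their steady states (signal, one-step noise, sensitivity, precision,
    spectral-gap adaptability, effective learning rates, subset conductance),
    Monte Carlo population simulations, a two-stage stochastic frontier
    optimizer that discovers reservoir/buffer/bottleneck structure, a dynamic
    probability-estimation benchmark against delta-rule and hierarchical
    Bayesian learners, and perturbation/graded-efficacy robustness analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
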