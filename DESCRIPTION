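Package: polexplore
Title: Policy Exploration and Value-Transfer Modelling of Multi-Dimensional
    Reward Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trial-by-trial computational modelling of behaviour in an
    uninstructed multi-dimensional reward learning task. Implements per-policy
    Rescorla-Wagner value learning with softmax choice, hidden-Markov and
    softmax-based inference of the feature-combination policy in use on each
    trial, entropy-based exploration statistics, a value-transfer learning
    model that initialises a newly adopted policy's value table from
    previously learned values, maximum-likelihood fitting with AIC/BIC model
    comparison, and a synthetic-agent simulator used for parameter- and
    model-recovery studies. Also exports unconvolved parametric regressor
    time series (value, reward prediction error, entropy, policy transition)
    for downstream neuroimaging analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
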