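Package: socialrl
Title: Simulation and Computational Modelling of Social Reinforcement
    Learning Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to simulate and model two social reinforcement learning
    paradigms: a social probabilistic selection task, in which neutral faces
    become happy or angry with fixed complementary probabilities and learning
    is described by a Q-learning model with separate reward and punishment
    learning rates, and a speech-expectancies task, in which single-shot
    update weights are estimated from pre-rating, false-feedback and
    post-rating triplets. Includes a synthetic-cohort generator with known
    ground-truth parameters, maximum-likelihood and hierarchical Bayesian
    model fitting, Pareto-smoothed importance-sampling leave-one-out model
    comparison (LOOIC), testing-phase accuracy metrics, influence-based
    outlier screening, and a mixed-effects inference stage with
    Tukey-adjusted marginal-mean contrasts and standardized effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
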