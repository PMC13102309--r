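Package: metarl
Title: Model-Based Metacognitive Efficiency for Reinforcement-Learning Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures metacognitive sensitivity and efficiency in value-based
    learning tasks where difficulty changes dynamically. Provides a two-armed
    reversal-bandit simulator, model-free Q-learning and hidden semi-Markov
    (model-based) learners, a Forward model fitted to choices by maximum
    likelihood and a Backward model fitted to confidence ratings by least
    squares, and the MetaRL.Ratio: the simulated performance of the Backward
    model divided by that of the Forward model. Includes quadratic scoring
    rule (QSR) and scaled-QSR calibration scores, confidence bias and
    autocorrelation summaries, chance-level exclusion filtering, and synthetic
    cohort generators for parameter-recovery, confidence-noise, and
    first-order independence validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
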