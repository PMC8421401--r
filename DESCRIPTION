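Package: spacedselect
Title: Machine-Learning Instruction Sequencing for Spaced Repetition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements an end-to-end toolkit for studying machine-learning
    based item selection in spaced-repetition learning. Provides the
    exponential forgetting-curve memory model with binary recalls and its
    count-based half-life-regression estimator, the closed-form optimal
    item-selection policy (SELECT) together with difficulty-ordered and
    uniform-random baseline policies, an in-silico randomized controlled
    trial simulator with known ground truth, and the trial evaluation
    statistics: empirical and normalized forgetting rates, controlled
    group comparisons via Mann-Whitney U tests with Bonferroni correction,
    robust (Huber) regression of the spacing effect, and engagement
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    MASS,
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
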