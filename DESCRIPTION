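Package: bltlearn
Title: Rescorla-Wagner Modelling of Continuous and Binary Responses in the
    Breathing Learning Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling associative learning in probabilistic
    cue-outcome tasks with bounded continuous (slider) or binary responses,
    built around the Breathing Learning Task (BLT). Implements Rescorla-Wagner
    prediction trajectories with single or valence-specific (dual) learning
    rates, a softmax observation model for binary predictions and a beta
    mean-dispersion observation model for continuous predictions, maximum a
    posteriori parameter estimation under Gaussian priors, null-model
    comparison via BIC/AIC and Bayes factors, simulation-based parameter
    recovery with Fisher-z averaged correlations, trial-schedule generation
    with probabilistic reversals, behavioural preprocessing (contingency-space
    coding, binarisation, certainty scores), and fully synthetic study
    generation for pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
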