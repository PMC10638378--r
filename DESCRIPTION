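Package: tsdpso
Title: Traction Switching-Delay Particle Swarm Optimization for Diagnostic SVM Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the traction switching-delay particle swarm optimizer
    (TSDPSO): a Markov-state-switching PSO variant with evolution-factor state
    estimation, state-dependent acceleration coefficients and velocity-update
    delays, and a traction operation that pulls long-stalled particles toward
    the delayed global best. Around the optimizer it provides the full
    diagnostic-classification pipeline used to tune RBF-kernel support vector
    machines on clinical tabular data: cleaning with z-score outlier removal,
    min-max normalization, PCA with explained-variance component selection,
    cross-validated hyperparameter search over (C, gamma), confusion-matrix
    metrics, ROC/PR curves, Pearson chi-square two-proportion model
    comparison, a suite of optimizer benchmark functions, and a synthetic
    cohort generator for fracture-related infection style datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
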