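Package: vametrics
Title: Chance-Corrected Accuracy Metrics for Verbal Autopsy Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual- and population-level accuracy metrics for validating
    cause-of-death assignment methods such as verbal autopsy classifiers.
    Implements cause-specific concordance, chance-corrected concordance (CCC),
    cause-specific mortality fraction (CSMF) accuracy, and chance-corrected
    CSMF accuracy (CCCSMF), together with the Random Allocation and
    Random-From-Train baseline predictors, uninformative-Dirichlet resampling
    of the test-set cause composition, and Monte Carlo calibration of the
    chance-correction constant. Works on long-format labelled deaths or
    pre-tabulated confusion matrices, returns tidy tibbles, and ships a small
    command-line interface for shell pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
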