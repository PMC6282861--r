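Package: enrichsel
Title: Design and Estimation for Clinical Trials with Subpopulation Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and evaluating single-stage and multistage
    (adaptive enrichment) clinical trials in which one of several nested
    candidate populations is selected by the maximum test statistic.
    Provides the joint density of the selected statistic and selection
    index, family-wise error rate calibrated critical values and
    O'Brien-Fleming or error-spending group-sequential boundaries,
    sample-size determination under two power definitions, a seeded
    Monte-Carlo trial simulator on sufficient statistics or patient-level
    data, and standardized bias / root-MSE assessment of the naive maximum
    likelihood estimator under selection and reporting conditioning.
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
    jsonlite,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
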