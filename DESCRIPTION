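Package: fibrodetect
Title: Scoring and Validation Analytics for a Fibromyalgia Screening
    Questionnaire
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for working with the FibroDetect fibromyalgia screening
    questionnaire: exact item coding and the 0-9 sum score with its
    completeness rule, per-item diagnostics (missing percentages, odds
    ratios with Woolf confidence intervals), partial least squares
    discriminant analysis with variable-importance-in-projection scores,
    an iterative multi-criteria item-reduction procedure, ROC/AUC analysis
    with integer-threshold selection under a sensitivity/specificity rule,
    and a latent-trait simulator that generates labelled synthetic
    respondent cohorts calibrated to published score distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
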