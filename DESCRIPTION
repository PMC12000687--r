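Package: facsimile
Title: Short-Form Questionnaire Construction by Lasso Item Selection and
    Re-Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives short versions of psychological questionnaire measures
    that accurately predict scores from the full-length measure (total sum
    scores, subscale sums, or factor scores from exploratory factor
    analysis). Implements the FACSIMILE procedure: per-dimension
    L1-regularized (Lasso) regression selects informative items, the union
    of selected items is re-weighted by unregularized per-dimension refits,
    and a randomized search over regularization strengths maps out the
    brevity/accuracy frontier. Includes a synthetic Likert-response
    generator with a known factor structure, train/validation/test
    utilities, a sample-size sensitivity bootstrap, spreadsheet-ready
    weight export, and a command-line interface.
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
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
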