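Package: basketdiet
Title: Agreement Between Grocery Purchase Records and Self-Reported Dietary Intake
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates purchased nutrients (energy, sugars, protein, fat,
    saturated fat and sodium) from supermarket loyalty-card transaction
    records via a product nutrient database with category-level generic
    imputation, converts household purchases to individual-level daily
    estimates by allocating nutrients proportional to age- and
    gender-specific recommended energy intakes, and quantifies agreement
    with food-frequency-questionnaire intake using Bland-Altman methods,
    including the regression approach to bias and limits of agreement on
    the log scale with back-transformed purchase:intake ratios. A
    synthetic-cohort generator with known ground-truth agreement structure
    stands in for confidential retailer and questionnaire data, making the
    full pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
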