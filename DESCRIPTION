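Package: itemforest
Title: Random-Forest Item Reduction for Ordinal Diagnostic Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks the ordinal items of clinician-administered diagnostic
    instruments (e.g., ADOS and ADI-R) by random-forest permutation
    importance, fits stepwise reduced-feature models under a held-out
    validation split with cross-validated testing, selects an optimal model
    by a weighted accuracy-versus-complexity score, and identifies the
    minimal model whose predictions are statistically indistinguishable from
    the full-feature model by McNemar's test. Includes a proportional-odds
    synthetic cohort generator for two-group ordinal item data so the whole
    procedure can be exercised and calibrated without access to clinical
    records, plus diagnostic accuracy metrics (AUC, sensitivity,
    specificity, Youden's J) and tidy/ggplot2 reporting.
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
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
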