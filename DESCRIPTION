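Package: stratarx
Title: Deconfounded Comparative Effectiveness of Antidepressants from
    Claims Data by Robust LASSO Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the comparative effectiveness of
    antidepressant monotherapies from insurance-claims-style data while
    controlling confounding by indication.  Builds treatment episodes from
    pharmacy fills, labels remission with a four-condition surrogate index
    (duration, therapeutic dose, no switch, no augmentation) with a
    clinician-code override, constructs episode-level binary predictor
    matrices over a one-year lookback with SAFE-style screening, selects
    sign-stable predictors of prescribing propensity and remission by
    bootstrapped cross-validated LASSO logistic regression, partitions
    episodes into importance-ordered strata with a minimum cell size, and
    estimates stratified effects via the Mantel-Haenszel common odds
    ratio with Robins-Breslow-Greenland confidence intervals and the
    Breslow-Day (Tarone-corrected) homogeneity test.  Includes a
    synthetic claims generator with planted propensity and remission
    structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    glmnet,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
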