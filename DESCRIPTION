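Package: metpanel
Title: Count-Rule Gene Expression and Methylation Panels for Predicting
    Metastasis in Clear Cell Renal Cell Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating multi-marker count-rule panels
    that predict distant metastasis in clear cell renal cell carcinoma from
    qPCR measurements. Converts raw cycle-threshold data to relative expression
    (delta-delta-Ct RQ, GAPDH-normalised against paired normal tissue) and to a
    methylation index (quantitative methylation-specific PCR, 0-100 percent)
    with bisulfite-conversion quality control; screens markers with the
    Mann-Whitney U test, Benjamini-Hochberg false-discovery-rate adjustment and
    univariate logistic regression; derives direction-aware ROC cutoffs by the
    Youden index with DeLong confidence intervals; and classifies samples by
    k-of-m marker-event count rules with full diagnostic performance reporting
    (sensitivity, specificity, predictive values with exact Clopper-Pearson
    intervals). A calibrated synthetic-cohort generator reproduces the
    statistical structure of a reference 80-patient cohort so the whole
    pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
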