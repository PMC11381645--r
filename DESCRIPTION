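Package: cgmscore
Title: Three-Dimensional Scoring of Continuous Glucose Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a three-dimensional clinical score from continuous
    glucose monitoring (CGM) time series. Daily low and high blood glucose
    indices (LBGI, HBGI) and the glycemic variability percentage (GVP) are
    min-max normalized to 0-100 hypoglycemia, hyperglycemia and variability
    scores, aggregated over multi-day windows with a weighted hypoglycemia
    dimension, and reduced to a single representative score with a
    color-coded segment. Includes raw CGM ingestion and 15-minute grid
    harmonization with availability filters, cohort-level calibration
    (percentile normalization fitting, consensus-target fulfillment, ROC
    cutoff selection, Spearman correlation matrices, polynomial models of
    AGP metrics on score), missing-data robustness experiments, and a
    seeded synthetic type 1 diabetes CGM cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, jsonlite, yaml
Suggests: testthat (>= 3.0.0), pROC, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
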