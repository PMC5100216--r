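Package: painscales
Title: Scoring and Validity Analysis of Behavioral Pain Scales in Intensive Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to score the Behavioral Pain Scale (BPS) and the
    Critical-Care Pain Observation Tool (CPOT), fuse them into a combined
    3-20 score with severity categories, and run a full validity battery
    on long-format intensive-care observation tables: paired Wilcoxon
    signed-rank tests for discriminant validity across nursing phases,
    Spearman rank correlation against the visual analog scale for
    criterion validity, ROC analysis with Youden-optimal cutoffs and
    prevalence-weighted accuracy, quadratic-weighted kappa agreement
    between the two instruments, and per-item Cohen effect sizes.
    Includes a seeded synthetic-cohort generator emulating a
    before/during/after nursing-procedure design so every pipeline stage
    can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
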