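Package: lipidcap
Title: Plasma Phospholipid Biomarker Discovery for Community-Acquired
    Pneumonia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical workflow for discovering plasma phospholipid
    biomarkers that separate community-acquired pneumonia (CAP) from
    infection-associated COPD exacerbation and from controls, using
    targeted lipidomic concentration panels (phosphatidylcholines,
    lysophosphatidylcholines, sphingomyelins, acylcarnitines, ceramides).
    Provides limit-of-detection quality filtering, covariate-regression
    imputation, derived metabolic indicators (class sums and ratios),
    nonparametric differential abundance with Benjamini-Hochberg
    correction, repeated stratified cross-validated ROC biomarker
    screening, a linear-fitting-slope / normalized-distance-to-fitting
    statistic for resolution markers over the CAP time course, PCA
    centroid trajectories, and correlation with inflammation markers.
    A seeded synthetic cohort generator emulating the study design makes
    the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
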