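Package: relapsig
Title: Multi-Omics Relapse Signature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A feature-selection pipeline for identifying minimal multi-omics
    panels that discriminate relapse from relapse-free patients in a two-group
    cohort design. Provides per-feature Welch t-test prefiltering, linear-SVM
    recursive feature elimination with Monte-Carlo two-fold cross-validation
    and leave-one-out validation, bootstrap ROC confidence intervals,
    chromosomal-instability (CIN) indices computed from copy-number segments
    at cytoband and chromosome resolution, relapse-exclusive rare-variant
    filtering with gene-level collapsing burden tests and gene-set
    aggregation, and random-forest integration of heterogeneous feature
    panels ranked against artificial contrasts, with Kendall tau-b
    association networks. A synthetic-cohort generator with planted
    differential signal makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
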