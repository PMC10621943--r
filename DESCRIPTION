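Package: stagemine
Title: Tumor Stage Discrimination and Association Rule Mining for Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable workflow for discriminating early-stage from late-stage
    tumors in bulk expression cohorts (FPKM-like sample-by-transcript matrices)
    and for mining the selected transcripts for stage-associated co-expression
    rules. Provides leakage-free nested cross-validation with per-fold cleaning
    and normalization, univariate Welch t-test filtering with cross-fold
    candidate pooling, wrapper feature selection by a binary elitist
    non-dominated sorting genetic algorithm (NSGA-II) driven by validation-fold
    AUC, multi-classifier evaluation (accuracy, AUC-ROC, per-class F1, MCC,
    sensitivity, specificity), FP-Growth frequent-itemset and association-rule
    mining over tertile-discretized expression with the stage label as an item,
    and rule analytics: stage-consequent rule extraction, per-transcript repeat
    counts, top rules by lift, phenotype-rule-feature graphs, and Spearman
    correlation tables. A seeded synthetic-cohort generator with planted
    differential signal, correlated blocks and constant features makes every
    stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    class,
    randomForest,
    igraph,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
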