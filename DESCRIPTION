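Package: adrhier
Title: Hierarchical Anatomical Coarse-Graining for Drug Side-Effect Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting adverse drug reactions from molecular
    descriptors under severe class imbalance. Side-effect labels from
    SIDER-style drug-event tables are coarse-grained through a curated
    three-level anatomical hierarchy (organ, sub-system, system), turning an
    intractable multi-label problem with thousands of sparse labels into a
    tractable one at each level. Includes one-vs-rest classification with a
    standard classifier suite and soft-voting ensemble, imbalance-robust
    evaluation (F2, AUC, AUPR and their composite Weighted Performance),
    a size-matched random-aggregation null control that isolates the value
    of anatomically meaningful grouping, and a synthetic data generator that
    emulates the skewed bipartite structure of real drug-event data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    glmnet,
    ranger,
    jsonlite,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
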