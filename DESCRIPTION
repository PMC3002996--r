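Package: acetr
Title: Dynamic Histone Acetylation Profiles and Their Coupling to Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for promoter histone-acetylation (H3K9,14ac)
    ChIP-chip time courses and matched gene-expression data over a
    differentiation time course. Calls per-probe acetylation states against a
    control-probe null with FDR control, summarizes probe-state transitions
    between days, converts probe-level signal to fixed-length binned TSS
    profiles with peak detection and peak-stability scoring, quantifies the
    coordination of acetylation change and expression change (day-pair
    correlation matrices with structure-preserving permutation tests,
    one-dimensional canonical correlation, shrinkage partial-correlation
    graphs), benchmarks a suite of classifiers for predicting expression-change
    class from acetylation-change profiles under balanced repeated
    cross-validation, and runs permutation-based gene-set enrichment analysis.
    Includes a synthetic-data generator emulating the statistical structure of
    such studies so every stage is testable without external data.
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
    rpart,
    randomForest,
    nnet,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
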