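Package: TRpredict
Title: Pathogenicity Prediction for Tandem Repeat Expansion Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies tandem repeat (TR) loci as pathogenic or benign when
    expanded. Converts BED-style TR loci into feature vectors combining binary
    annotation overlaps, genic context, gene constraint scores, motif
    composition and star-network topological indices; trains a calibrated
    SVM + gradient-boosted tree ensemble with leave-one-out cross-validation;
    and provides the companion statistics: interval-overlap Fisher enrichment
    with conditional-MLE odds ratios, confusion-matrix and ROC/PRC metrics,
    age-of-onset correlation, and an anchored in-repeat-read outlier pipeline
    for detecting rare repeat expansions against a control cohort. Ships
    synthetic-data generators and a packaged catalog of known pathogenic TR
    loci so every component is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    igraph,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
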