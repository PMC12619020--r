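Package: putsense
Title: Detecting Rare Perceived-Unfair-Treatment Days from Passive Mobile Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting rare self-reported
    "perceived unfair treatment" (PUT) days from passively sensed
    smartphone and wearable behavior. Provides a seeded synthetic cohort
    generator (event-level sensor streams, EMA labels, ground truth),
    epoch-based behavioral feature extraction, dataset assembly with
    availability filters and leakage-safe chronological splits, a
    user-independent classification benchmark under nested stratified
    group cross-validation, a user-dependent masked LSTM-autoencoder
    anomaly detector with percentile thresholding, and rare-event
    evaluation statistics (AUROC/AUPR, paired one-sided Wilcoxon tests
    with Benjamini-Hochberg correction, standardized mean differences).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    class,
    e1071,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
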