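Package: histobag
Title: Histogram-Based Bag-of-Tiles Classification of Whole-Slide Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares fully supervised, weakly supervised (multiple-instance
    and EM discriminative-patch selection) and unsupervised (bag-of-features
    with k-means or Gaussian-mixture codebooks) tile-level feature
    representations for whole-slide histopathology classification. Slides are
    treated as bags of fixed-size tiles; each representation maps tiles to a
    concept vocabulary, slides are encoded as normalized concept-frequency
    histograms, and a decision-fusion classifier (SVM or random forest)
    predicts the slide label under patient-grouped cross-validation.
    Class-specific interpretability is provided through probability heatmaps
    and permutation-importance propagation onto tiles. Includes a seeded
    synthetic slide-cohort generator that plants minority lesion regions in
    diseased slides so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    e1071,
    randomForest,
    pROC,
    png,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
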