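test_that("patient-grouped folds partition patients with near-equal sizes", {
  pats10 <- sprintf("P%02d", 1:10)
  f <- patient_grouped_folds(pats10, k = 10, seed = 1)
  expect_equal(sort(f), 1:10)

  # 23 patients over 10 folds: seven folds of 2 and three of 3
  pats23 <- rep(sprintf("P%02d", 1:23), times = rep(c(2, 3), length.out = 23))
  f23 <- patient_grouped_folds(pats23, k = 10, seed = 4)
  per_pat <- tapply(f23, pats23, unique)
  expect_true(all(lengths(per_pat) == 1))      # no patient straddles folds
  sizes <- sort(as.vector(table(unlist(per_pat))))
  expect_equal(sizes, c(rep(2, 7), rep(3, 3)))

  expect_identical(patient_grouped_folds(pats23, 10, 9),
                   patient_grouped_folds(pats23, 10, 9))
  expect_error(patient_grouped_folds(pats10[1:5], k = 10), "at least")
})

test_that("fusion classifiers separate one-hot histograms and are seeded", {
  H <- diag(3)[rep(1:3, each = 8), ]
  labels <- rep(c("a", "b", "c"), each = 8)
  for (kind in c("svm", "rf")) {
    m <- train_fusion_classifier(H, labels, kind, seed = 6)
    pred <- predict_slide(m, H)
    expect_equal(pred$label, labels)
    expect_equal(dim(pred$scores), c(24L, 3L))
    # argmax consistency
    expect_equal(pred$label,
                 colnames(pred$scores)[max.col(pred$scores,
                                               ties.method = "first")])
    m2 <- train_fusion_classifier(H, labels, kind, seed = 6)
    withr::with_seed(31, Hnew <- matrix(stats::runif(30), 10, 3))
    expect_identical(predict_slide(m, Hnew), predict_slide(m2, Hnew))
  }
  expect_error(train_fusion_classifier(H, labels, "boost"), "kind")
  expect_error(train_fusion_classifier(H, rep("a", 24), "rf"), "two classes")
  m <- train_fusion_classifier(H, labels, "rf", seed = 1)
  expect_error(predict_slide(m, matrix(0, 2, 5)), "length")
})

test_that("random forest recalls a unique training exemplar", {
  withr::with_seed(17, H <- matrix(stats::runif(60), 20, 3))
  labels <- rep(c("x", "y"), each = 10)
  m <- train_fusion_classifier(H, labels, "rf", seed = 2)
  pred <- predict_slide(m, H[3, ])
  expect_equal(pred$label, "x")
})

test_that("cross-validation metrics: perfect predictor, clipping, prevalence identities", {
  # perfectly separable histograms, patient-grouped
  withr::with_seed(23, {
    pats <- rep(sprintf("P%02d", 1:20), each = 2)
    labels <- rep(rep(c("a", "b", "c"), length.out = 20), each = 2)
    H <- diag(3)[match(labels, c("a", "b", "c")), ] +
      matrix(stats::runif(120, 0, 0.05), 40, 3)
  })
  rep_perf <- suppressWarnings(
    evaluate_cv(H, labels, pats, "rf", k = 10, seed = 3))
  for (mt in c("accuracy", "auc", "precision", "recall", "f1")) {
    v <- report_metric(rep_perf, mt)
    expect_equal(unname(v), c(1, 1, 1), tolerance = 1e-12)
  }
  expect_true(all(rep_perf$metrics$ci_hi <= 1))
  expect_true(all(rep_perf$metrics$ci_lo >= 0, na.rm = TRUE))

  # degenerate always-predict-one-class metrics via the internal fold scorer
  truth <- c("a", "a", "b", "b", "b", "c")
  pred <- rep("b", 6)
  scores <- matrix(0, 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  scores[, "b"] <- 1
  fm <- histobag:::fold_class_metrics(truth, pred, scores, c("a", "b", "c"))
  expect_equal(fm$recall[fm$class == "b"], 1)
  expect_equal(fm$recall[fm$class == "a"], 0)
  expect_equal(fm$recall[fm$class == "weighted"], 0.5)  # prevalence of b
  expect_equal(fm$accuracy[fm$class == "weighted"], 0.5)
})

test_that("cross-validation is invariant to slide order for a deterministic model", {
  withr::with_seed(29, {
    pats <- rep(sprintf("P%02d", 1:15), each = 2)
    labels <- rep(rep(c("a", "b", "c"), 5), each = 2)
    H <- diag(3)[match(labels, c("a", "b", "c")), ] +
      matrix(stats::runif(90, 0, 0.2), 30, 3)
    perm <- sample.int(30)
  })
  r1 <- suppressWarnings(evaluate_cv(H, labels, pats, "svm", k = 5, seed = 7))
  r2 <- suppressWarnings(evaluate_cv(H[perm, ], labels[perm], pats[perm],
                                     "svm", k = 5, seed = 7))
  expect_equal(report_metric(r1, "accuracy"), report_metric(r2, "accuracy"),
               tolerance = 1e-10)
  expect_equal(report_metric(r1, "f1"), report_metric(r2, "f1"),
               tolerance = 1e-10)
})

test_that("PCA projection is centered with ordered axis variances", {
  withr::with_seed(37, H <- matrix(stats::runif(60), 20, 3))
  xy <- project_histograms_pca(H)
  expect_equal(dim(xy), c(20L, 2L))
  expect_equal(unname(colMeans(xy)), c(0, 0), tolerance = 1e-12)
  expect_gte(stats::var(xy[, 1]), stats::var(xy[, 2]))
  expect_error(project_histograms_pca(H[1:2, ]), "at least 3")
})

test_that("model grid shares one fold assignment and validates ids", {
  co <- small_cohort()
  grid <- suppressWarnings(
    run_model_grid(co, c("MIL-RF", "MIL-SVM"),
                   grid_config(k_folds = 5, seed = 13,
                               classifier = classifier_config(seed = 13,
                                                              epochs = 15))))
  expect_named(grid$reports, c("MIL-RF", "MIL-SVM"))
  expect_identical(grid$reports[["MIL-RF"]]$folds,
                   grid$reports[["MIL-SVM"]]$folds)
  expect_identical(grid$folds, grid$reports[["MIL-RF"]]$folds)
  expect_error(run_model_grid(co, "CNN-RF"), "unknown model id")

  single <- suppressWarnings(
    run_model_grid(co, "MIL-RF",
                   grid_config(k_folds = 5, seed = 13,
                               classifier = classifier_config(seed = 13,
                                                              epochs = 15))))
  expect_named(single$reports, "MIL-RF")
})
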