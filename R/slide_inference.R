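#' Patient-grouped fold assignment
#'
#' Partitions patients (not slides) into k folds of near-equal size (sizes
#' differ by at most one); every slide inherits its patient's fold, so no
#' patient ever straddles folds. Deterministic given the seed.
#'
#' @param manifest data.frame with a `patient_id` column (one row per
#'   slide), or a character vector of per-slide patient ids.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer fold id (1..k) per slide.
#' @export
patient_grouped_folds <- function(manifest, k = 10L, seed = 1L) {
  patients <- if (is.data.frame(manifest)) manifest$patient_id else manifest
  ids <- unique(patients)
  if (length(ids) < k)
    stop(sprintf("need at least %d patients for %d folds", k, k))
  withr::with_seed(seed, {
    shuffled <- sample(ids)
    sizes <- rep(length(ids) %/% k, k)
    extra <- length(ids) %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    fold_of <- rep(seq_len(k), times = sizes)
    fold_of[match(patients, shuffled)]
  })
}

#' Train a decision-fusion slide classifier
#'
#' Fits the slide-level classifier on concept histograms. `kind = "svm"`
#' trains one RBF support-vector machine per class (one-vs-rest) and scores
#' slides by signed decision values, oriented so larger means more likely
#' the class; `kind = "rf"` trains a 500-tree random forest and scores by
#' class vote fractions. Both are seeded.
#'
#' @param histograms matrix `n_slides x K`.
#' @param labels slide labels (>= 2 classes).
#' @param kind `"svm"` or `"rf"`.
#' @param seed integer seed.
#' @return A `fusion_classifier`.
#' @export
train_fusion_classifier <- function(histograms, labels,
                                    kind = c("svm", "rf"), seed = 1L) {
  if (is.character(kind) && length(kind) == 1 && !kind %in% c("svm", "rf"))
    stop(sprintf("unknown classifier kind '%s'", kind))
  kind <- match.arg(kind)
  h <- as.matrix(histograms)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need slides from at least two classes")
  colnames(h) <- paste0("c", seq_len(ncol(h)))
  model <- withr::with_seed(seed, {
    if (kind == "svm") {
      # variance-scaled bandwidth: histogram entries shrink like 1/K, so a
      # fixed 1/p gamma would flatten the kernel for large vocabularies
      gamma <- 1 / (ncol(h) * max(mean(apply(h, 2, stats::var)), 1e-12))
      lapply(levels(labels), function(cl) {
        y <- factor(ifelse(labels == cl, "pos", "neg"),
                    levels = c("pos", "neg"))
        fit <- e1071::svm(x = h, y = y, kernel = "radial", scale = FALSE,
                          gamma = gamma)
        dv <- attr(stats::predict(fit, h, decision.values = TRUE),
                   "decision.values")[, 1]
        sgn <- if (mean(dv[y == "pos"]) >= mean(dv[y == "neg"])) 1 else -1
        list(fit = fit, sign = sgn)
      })
    } else {
      randomForest::randomForest(x = h, y = labels, ntree = 500)
    }
  })
  structure(list(kind = kind, model = model, classes = levels(labels),
                 n_features = ncol(h), seed = as.integer(seed)),
            class = "fusion_classifier")
}

#' Predict slide labels and per-class scores
#'
#' The label is the argmax of the per-class scores; the scores support
#' one-vs-rest ROC analysis (SVM decision values or random-forest vote
#' fractions).
#'
#' @param model a `fusion_classifier`.
#' @param histograms histogram vector (one slide) or matrix.
#' @return List with `label` (character vector) and `scores`
#'   (`n x n_classes` matrix).
#' @export
predict_slide <- function(model, histograms) {
  stopifnot(inherits(model, "fusion_classifier"))
  h <- if (is.matrix(histograms)) histograms else matrix(histograms, nrow = 1)
  if (ncol(h) != model$n_features)
    stop("histogram length does not match the trained model")
  colnames(h) <- paste0("c", seq_len(ncol(h)))
  scores <- if (model$kind == "svm") {
    s <- vapply(model$model, function(m)
      m$sign * attr(stats::predict(m$fit, h, decision.values = TRUE),
                    "decision.values")[, 1],
      numeric(nrow(h)))
    matrix(s, nrow = nrow(h), dimnames = list(NULL, model$classes))
  } else {
    p <- stats::predict(model$model, h, type = "prob")
    p[, model$classes, drop = FALSE]
  }
  list(label = model$classes[max.col(scores, ties.method = "first")],
       scores = scores)
}

# per-class one-vs-rest metrics for one held-out fold
fold_class_metrics <- function(truth, pred, scores, classes) {
  rows <- lapply(classes, function(cl) {
    yt <- truth == cl
    yp <- pred == cl
    support <- sum(yt)
    tp <- sum(yt & yp); fp <- sum(!yt & yp); fn <- sum(yt & !yp)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (support > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall)
    else if (is.na(recall)) NA_real_ else 0
    auc <- if (support > 0 && support < length(yt)) {
      as.numeric(pROC::auc(pROC::roc(
        response = yt, predictor = scores[, cl],
        levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
    } else NA_real_
    data.frame(class = cl, support = support,
               accuracy = mean(yt == yp), auc = auc,
               precision = precision, recall = recall, f1 = f1,
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  wt <- per_class$support / sum(per_class$support)
  wavg <- function(v) {
    ok <- !is.na(v) & wt > 0
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * wt[ok]) / sum(wt[ok])
  }
  weighted <- data.frame(
    class = "weighted", support = sum(per_class$support),
    accuracy = mean(truth == pred),     # overall multiclass accuracy
    auc = wavg(per_class$auc), precision = wavg(per_class$precision),
    recall = wavg(per_class$recall), f1 = wavg(per_class$f1),
    stringsAsFactors = FALSE)
  rbind(per_class, weighted)
}

#' Patient-grouped cross-validation of a fusion classifier
#'
#' For each fold: fit on the remaining folds, score the held-out slides,
#' compute per-class one-vs-rest metrics (binarized accuracy, AUC from
#' per-class scores, precision, recall, F1) and their support-weighted
#' average; the weighted accuracy is the overall multiclass accuracy (the
#' support-weighted recall). Fold means are reported with 95% t confidence
#' intervals `mean +/- t(0.975, m-1) sd / sqrt(m)` over the m folds where
#' the metric is defined, clipped to \[0, 1\]. A fold missing a class yields an
#' undefined AUC for that class; such folds are excluded from that class's
#' mean with a warning.
#'
#' @param histograms matrix `n_slides x K`.
#' @param labels slide labels.
#' @param patients per-slide patient ids.
#' @param kind `"svm"` or `"rf"`.
#' @param k number of folds.
#' @param seed seed for fold assignment and classifier fits.
#' @param folds optional precomputed fold assignment (shared across models).
#' @param model_id identifier recorded in the report.
#' @return A `cv_report`: list with `metrics` (class x metric summary with
#'   CI), `per_fold`, `folds`, `model_id`.
#' @export
evaluate_cv <- function(histograms, labels, patients, kind = c("svm", "rf"),
                        k = 10L, seed = 1L, folds = NULL, model_id = NULL) {
  kind <- match.arg(kind)
  h <- as.matrix(histograms)
  labels <- as.character(labels)
  stopifnot(nrow(h) == length(labels), length(labels) == length(patients))
  if (is.null(folds)) folds <- patient_grouped_folds(patients, k, seed)
  k <- max(folds)
  classes <- sort(unique(labels))

  per_fold <- lapply(seq_len(k), function(f) {
    tr <- folds != f; te <- folds == f
    model <- train_fusion_classifier(h[tr, , drop = FALSE], labels[tr],
                                     kind, seed = seed)
    pred <- predict_slide(model, h[te, , drop = FALSE])
    cbind(fold = f,
          fold_class_metrics(labels[te], pred$label, pred$scores, classes))
  })
  per_fold <- do.call(rbind, per_fold)

  metric_names <- c("accuracy", "auc", "precision", "recall", "f1")
  summary_rows <- list()
  n_undef_auc <- 0L
  for (cl in c(classes, "weighted")) {
    sub <- per_fold[per_fold$class == cl, ]
    for (mn in metric_names) {
      v <- sub[[mn]]
      if (mn == "auc") n_undef_auc <- n_undef_auc + sum(is.na(v) & cl != "weighted")
      v <- v[!is.na(v)]
      m <- length(v)
      if (m == 0) {
        mu <- NA_real_; lo <- NA_real_; hi <- NA_real_
      } else if (m == 1) {
        mu <- v; lo <- clip01(v); hi <- clip01(v)
      } else {
        mu <- mean(v)
        half <- stats::qt(0.975, m - 1) * stats::sd(v) / sqrt(m)
        lo <- clip01(mu - half); hi <- clip01(mu + half)
      }
      summary_rows[[length(summary_rows) + 1L]] <-
        data.frame(class = cl, metric = mn, mean = mu,
                   ci_lo = lo, ci_hi = hi, n_folds = m,
                   stringsAsFactors = FALSE)
    }
  }
  if (n_undef_auc > 0)
    warning(sprintf("AUC undefined in %d fold/class combinations (class absent from fold); excluded from fold means",
                    n_undef_auc))
  structure(list(metrics = do.call(rbind, summary_rows),
                 per_fold = per_fold, folds = folds,
                 model_id = model_id %||% toupper(kind), kind = kind, k = k),
            class = "cv_report")
}

#' Extract one summary metric from a CV report
#'
#' @param report a `cv_report`.
#' @param metric one of accuracy, auc, precision, recall, f1.
#' @param class a class name or `"weighted"`.
#' @return Named numeric `c(mean, ci_lo, ci_hi)`.
#' @export
report_metric <- function(report, metric = "accuracy", class = "weighted") {
  row <- report$metrics[report$metrics$class == class &
                        report$metrics$metric == metric, ]
  if (nrow(row) != 1) stop("no such metric in report")
  c(mean = row$mean, ci_lo = row$ci_lo, ci_hi = row$ci_hi)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("CV report [%s], %d folds\n", x$model_id, x$k))
  w <- x$metrics[x$metrics$class == "weighted", ]
  for (i in seq_len(nrow(w)))
    cat(sprintf("  weighted %-9s %.3f [%.3f, %.3f]\n",
                w$metric[i], w$mean[i], w$ci_lo[i], w$ci_hi[i]))
  invisible(x)
}

#' 2-D PCA projection of slide histograms
#'
#' Mean-centered scores on the top two principal axes, used to visualize how
#' separably each representation encodes the slide classes.
#'
#' @param histograms matrix `n_slides x K` (n >= 3).
#' @return Matrix `n x 2` of PC scores.
#' @export
project_histograms_pca <- function(histograms) {
  h <- as.matrix(histograms)
  if (nrow(h) < 3) stop("need at least 3 slides for a PCA projection")
  pr <- stats::prcomp(h, center = TRUE, scale. = FALSE)
  scores <- pr$x
  if (ncol(scores) < 2)
    scores <- cbind(scores, matrix(0, nrow(scores), 2 - ncol(scores)))
  out <- scores[, 1:2, drop = FALSE]
  colnames(out) <- c("PC1", "PC2")
  out
}

#' The ten-model comparison grid
#' @export
model_grid_ids <- function() {
  c("FS-RF", "FS-SVM", "MIL-RF", "MIL-SVM", "EM-RF", "EM-SVM",
    "KM-RF", "KM-SVM", "GMM-RF", "GMM-SVM")
}

#' Configuration for [run_model_grid()]
#'
#' @param k_folds CV folds.
#' @param seed grid seed (fold assignment and all model fits).
#' @param embed_dim autoencoder embedding dimension for the codebook routes.
#' @param K_gmm,K_km_svm,K_km_rf codebook sizes (defaults follow the
#'   selected operating points: 150 for GMM, 200 for KM with SVM, 100 for KM
#'   with RF).
#' @param classifier tile-classifier config (FS/MIL/EM routes).
#' @param autoencoder autoencoder config (codebook routes).
#' @param em EM config (threshold/smoothing/convergence).
#' @param min_coverage mask coverage for FS tile labels.
#' @param min_tissue,background_threshold tiling options.
#' @param train_cohort optional separate cohort used to train the tile-level
#'   models (mirrors holding out an annotated training set); defaults to the
#'   evaluation cohort itself.
#' @return A config list.
#' @export
grid_config <- function(k_folds = 10L, seed = 1L, embed_dim = 32L,
                        K_gmm = 150L, K_km_svm = 200L, K_km_rf = 100L,
                        classifier = classifier_config(),
                        autoencoder = autoencoder_config(),
                        em = NULL, min_coverage = 0.5,
                        min_tissue = 0.5, background_threshold = 0.9,
                        train_cohort = NULL) {
  cfg <- as.list(environment())
  cfg$em <- em %||% em_config(classifier = classifier)
  cfg
}

#' Run the model comparison grid
#'
#' Encodes the cohort once per representation route (FS, MIL, EM, KM, GMM)
#' and cross-validates a fusion classifier per requested model id. All
#' models share one patient-grouped fold assignment for a fair comparison.
#'
#' @param cohort evaluation `wsi_cohort`.
#' @param model_ids subset of [model_grid_ids()].
#' @param config a [grid_config()].
#' @return A `model_grid`: list with `reports` (named `cv_report`s), shared
#'   `folds`, per-route `histograms`, and slide `meta`.
#' @export
run_model_grid <- function(cohort, model_ids = model_grid_ids(),
                           config = grid_config()) {
  bad <- setdiff(model_ids, model_grid_ids())
  if (length(bad) > 0)
    stop(sprintf("unknown model id(s): %s", paste(bad, collapse = ", ")))
  routes <- unique(sub("-(RF|SVM)$", "", model_ids))

  ct_eval <- cohort_tiles(cohort, min_tissue = config$min_tissue,
                          background_threshold = config$background_threshold)
  desc_eval <- tile_descriptors(ct_eval$tiles, config$classifier$n_freq,
                                config$classifier$n_orient)
  sids <- unique(ct_eval$index$slide_id)
  meta <- ct_eval$index[match(sids, ct_eval$index$slide_id),
                        c("slide_id", "patient_id", "label")]
  train_cohort <- config$train_cohort %||% cohort
  ct_train <- if (is.null(config$train_cohort)) ct_eval
              else cohort_tiles(train_cohort, min_tissue = config$min_tissue,
                                background_threshold = config$background_threshold)

  folds <- patient_grouped_folds(meta$patient_id, config$k_folds, config$seed)

  histograms <- list()
  for (route in routes) {
    histograms[[route]] <- switch(route,
      "FS" = {
        fs <- build_fs_tileset(train_cohort, config$min_coverage,
                               min_tissue = config$min_tissue,
                               background_threshold = config$background_threshold)
        clf <- train_tile_classifier(fs$tiles, fs$labels, config$classifier)
        slide_histograms(predict_concept_probabilities(clf, desc_eval),
                         ct_eval$index$slide_id)
      },
      "MIL" = {
        mil <- build_mil_tileset(ct_train)
        clf <- train_tile_classifier(mil$tiles, mil$labels, config$classifier)
        slide_histograms(predict_concept_probabilities(clf, desc_eval),
                         ct_eval$index$slide_id)
      },
      "EM" = {
        fit <- em_train(ct_train, config$em)
        slide_histograms(predict_concept_probabilities(fit$classifier, desc_eval),
                         ct_eval$index$slide_id)
      },
      "KM" = ,
      "GMM" = {
        ae <- train_autoencoder(ct_train$tiles, config$embed_dim,
                                config$autoencoder)
        emb_train <- embed_tiles(ae, ct_train$tiles)
        emb_eval <- embed_tiles(ae, desc_eval)
        if (route == "GMM") {
          cb <- fit_gmm_codebook(emb_train, config$K_gmm, seed = config$seed)
          slide_histograms(gmm_posterior(cb, emb_eval),
                           ct_eval$index$slide_id)
        } else {
          list(
            svm = {
              cb <- fit_kmeans_codebook(emb_train, config$K_km_svm,
                                        seed = config$seed)
              slide_histograms_hard(hard_assign(cb, emb_eval),
                                    ct_eval$index$slide_id, config$K_km_svm)
            },
            rf = {
              cb <- fit_kmeans_codebook(emb_train, config$K_km_rf,
                                        seed = config$seed)
              slide_histograms_hard(hard_assign(cb, emb_eval),
                                    ct_eval$index$slide_id, config$K_km_rf)
            })
        }
      })
  }

  reports <- list()
  for (id in model_ids) {
    route <- sub("-(RF|SVM)$", "", id)
    kind <- tolower(sub("^.*-", "", id))
    H <- histograms[[route]]
    if (route == "KM") H <- H[[kind]]
    reports[[id]] <- evaluate_cv(H, meta$label, meta$patient_id, kind,
                                 k = config$k_folds, seed = config$seed,
                                 folds = folds, model_id = id)
  }
  structure(list(reports = reports, folds = folds,
                 histograms = histograms, meta = meta),
            class = "model_grid")
}
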