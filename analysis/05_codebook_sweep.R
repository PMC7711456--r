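#!/usr/bin/env Rscript
# Step 5: codebook-size sweep for the unsupervised routes.
#
# Re-encodes the evaluation cohort for a grid of codebook sizes (k-means
# hard assignment and GMM soft assignment) and records the weighted AUC of
# the cross-validated fusion classifier at each K. The default grid is kept
# to desk scale; the full span 3..300 is available via the K grid argument.

suppressPackageStartupMessages(library(histobag))

cohorts <- readRDS("scratch/cohorts/cohorts.rds")
models <- readRDS("scratch/tile_models.rds")

ct <- cohort_tiles(cohorts$eval)
emb <- embed_tiles(models$autoencoder, ct$tiles)
meta <- ct$index[match(unique(ct$index$slide_id), ct$index$slide_id),
                 c("slide_id", "patient_id", "label")]
folds <- patient_grouped_folds(meta$patient_id, 10, seed = 17)

K_grid <- c(3, 5, 10, 20, 50, 100, 150)

make_eval <- function(kind_cb, kind_clf) {
  function(cb, K) {
    H <- if (kind_cb == "gmm")
      slide_histograms(gmm_posterior(cb, emb), ct$index$slide_id)
    else
      slide_histograms_hard(hard_assign(cb, emb), ct$index$slide_id, K)
    r <- suppressWarnings(evaluate_cv(H, meta$label, meta$patient_id,
                                      kind_clf, k = 10, seed = 17,
                                      folds = folds))
    v <- report_metric(r, "auc")
    c(weighted_auc = v[["mean"]], ci_lo = v[["ci_lo"]], ci_hi = v[["ci_hi"]])
  }
}

tabs <- list()
for (combo in list(c("km", "rf"), c("km", "svm"),
                   c("gmm", "rf"), c("gmm", "svm"))) {
  message("sweeping ", combo[1], " + ", combo[2], " ...")
  tab <- sweep_codebook_sizes(emb, K_grid,
                              make_eval(combo[1], combo[2]),
                              kind = combo[1], seed = 17)
  tabs[[paste(combo, collapse = "_")]] <-
    cbind(clustering = combo[1], classifier = combo[2], tab)
}
out <- do.call(rbind, tabs)
write.csv(out, "results/05_codebook_sweep.csv", row.names = FALSE)
print(out, row.names = FALSE, digits = 3)

# At the default noise the classes separate so cleanly that even K = 3 is
# perfect; probe whether vocabulary size starts to matter under heavier
# class overlap. (Observed: it does not on this generator — averaging ~50
# tiles per slide absorbs tile-level noise, the robustness that motivates
# decision fusion in the first place.)
message("companion sweep at texture_noise = 0.6 ...")
noisy <- generate_cohort(cohort_params(texture_noise = 0.6, seed = 101L))
ctn <- cohort_tiles(noisy)
aen <- train_autoencoder(ctn$tiles, 32, autoencoder_config(seed = 2))
embn <- embed_tiles(aen, ctn$tiles)
metan <- ctn$index[match(unique(ctn$index$slide_id), ctn$index$slide_id),
                   c("slide_id", "patient_id", "label")]
foldsn <- patient_grouped_folds(metan$patient_id, 10, seed = 17)
eval_noisy <- function(cb, K) {
  H <- slide_histograms(gmm_posterior(cb, embn), ctn$index$slide_id)
  r <- suppressWarnings(evaluate_cv(H, metan$label, metan$patient_id, "rf",
                                    k = 10, seed = 17, folds = foldsn))
  v <- report_metric(r, "auc")
  c(weighted_auc = v[["mean"]], ci_lo = v[["ci_lo"]], ci_hi = v[["ci_hi"]])
}
tab_noisy <- sweep_codebook_sizes(embn, K_grid, eval_noisy, kind = "gmm",
                                  seed = 17)
write.csv(tab_noisy, "results/05_codebook_sweep_noisy.csv",
          row.names = FALSE)
print(tab_noisy, row.names = FALSE, digits = 3)
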