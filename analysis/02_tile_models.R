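#!/usr/bin/env Rscript
# Step 2: train the tile-level models on the training cohort.
#
# Trains (a) the softmax tile classifier on MIL labels (tiles inherit their
# slide's diagnosis) and, for reference, on ground-truth tile labels, and
# (b) the unsupervised tile autoencoder. Reports held-out tile accuracy and
# reconstruction error against the constant mean-image baseline.

suppressPackageStartupMessages(library(histobag))

cohorts <- readRDS("scratch/cohorts/cohorts.rds")
ct <- cohort_tiles(cohorts$train)
desc <- tile_descriptors(ct$tiles)
message(length(ct$tiles), " training tiles")

set.seed(42)
keep <- which(ct$index$truth != "background")
tr <- sample(keep, floor(0.7 * length(keep)))
te <- setdiff(keep, tr)

rows <- list()

# truth-labeled (fully supervised analogue of annotated regions)
clf_fs <- train_tile_classifier(desc[tr, ], ct$index$truth[tr],
                                classifier_config(seed = 1))
P <- predict_concept_probabilities(clf_fs, desc[te, ])
rows$fs <- data.frame(model = "classifier_truth_labels",
                      metric = "holdout_tile_accuracy",
                      value = mean(colnames(P)[max.col(P)] ==
                                     ct$index$truth[te]))

# MIL-labeled (weak labels: slide diagnosis per tile)
mil <- build_mil_tileset(ct)
clf_mil <- train_tile_classifier(desc, mil$labels, classifier_config(seed = 1))
Pm <- predict_concept_probabilities(clf_mil, desc[te, ])
rows$mil <- data.frame(model = "classifier_mil_labels",
                       metric = "holdout_truth_accuracy",
                       value = mean(colnames(Pm)[max.col(Pm)] ==
                                      ct$index$truth[te]))

# autoencoder
ae <- train_autoencoder(ct$tiles, 32, autoencoder_config(seed = 2))
n <- length(ct$tiles)
rec <- reconstruct_tiles(ae, ct$tiles)
mean_img <- Reduce(`+`, ct$tiles) / n
err_rec <- mean(vapply(seq_len(n), function(i)
  mean((rec[[i]] - ct$tiles[[i]])^2), numeric(1)))
err_const <- mean(vapply(seq_len(n), function(i)
  mean((mean_img - ct$tiles[[i]])^2), numeric(1)))
rows$ae <- data.frame(model = c("autoencoder", "mean_image_baseline"),
                      metric = "reconstruction_mse",
                      value = c(err_rec, err_const))

tab <- do.call(rbind, rows)
write.csv(tab, "results/02_tile_models.csv", row.names = FALSE)
print(tab, row.names = FALSE)

saveRDS(list(classifier_mil = clf_mil, classifier_fs = clf_fs,
             autoencoder = ae),
        "scratch/tile_models.rds")
message("tile models cached under scratch/tile_models.rds")
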