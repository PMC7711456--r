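#!/usr/bin/env Rscript
# Step 6: class-specific heatmaps and localization scoring.
#
# For the unsupervised GMM route: permutation importance of each codeblock
# for the diseased class, propagated onto tiles via their codeblock
# posteriors; for the weakly supervised routes: direct class-probability
# heatmaps. Both are scored against the planted lesion regions (ranking
# lesion vs benign tiles within diseased slides) and example overlays are
# rendered as PNG.

suppressPackageStartupMessages(library(histobag))

cohorts <- readRDS("scratch/cohorts/cohorts.rds")
models <- readRDS("scratch/tile_models.rds")
ct <- cohort_tiles(cohorts$eval)
desc <- tile_descriptors(ct$tiles)

emb <- embed_tiles(models$autoencoder, desc)
cb <- fit_gmm_codebook(emb, 150, seed = 19)
post <- gmm_posterior(cb, emb)
H <- slide_histograms(post, ct$index$slide_id)
meta <- ct$index[match(rownames(H), ct$index$slide_id),
                 c("slide_id", "patient_id", "label")]

fm <- train_fusion_classifier(H, meta$label, "rf", seed = 19)
imp <- permutation_importance(fm, H, meta$label, "dysplastic",
                              repeats = 10, seed = 23)
ti <- tile_importance(post, imp)

loc_auc <- function(score) {
  diseased <- ct$index$label == "dysplastic"
  lesion <- ct$index$truth[diseased] == "dysplastic"
  as.numeric(pROC::auc(pROC::roc(response = lesion,
                                 predictor = score[diseased],
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

P_mil <- predict_concept_probabilities(models$classifier_mil, desc)
scores <- data.frame(
  route = c("GMM_permutation_importance", "MIL_class_probability"),
  localization_auc = c(loc_auc(ti), loc_auc(P_mil[, "dysplastic"])))
write.csv(scores, "results/06_localization_auc.csv", row.names = FALSE)
message("lesion localization (ranking lesion vs benign tiles in diseased slides):")
print(scores, row.names = FALSE, digits = 3)

# render one diseased slide's heatmap for each route
dir.create("scratch/figures", recursive = TRUE, showWarnings = FALSE)
sid <- meta$slide_id[meta$label == "dysplastic"][1]
sel <- ct$index$slide_id == sid
ld <- attr(ct, "lattice_dim")
map_gmm <- importance_map(ti[sel], ct$index[sel, ], ld)
map_mil <- importance_map(P_mil[sel, "dysplastic"], ct$index[sel, ], ld)
render_heatmap(map_gmm, attr(ct, "tile_size"),
               path = file.path("scratch/figures",
                                paste0("heatmap_gmm_", sid, ".png")))
render_heatmap(map_mil, attr(ct, "tile_size"),
               path = file.path("scratch/figures",
                                paste0("heatmap_mil_", sid, ".png")))
raw <- data.frame(ct$index[sel, c("slide_id", "row", "col")],
                  importance = ti[sel], class = "dysplastic")
write.csv(raw, "results/06_heatmap_values.csv", row.names = FALSE)
message("example overlays written under scratch/figures/")
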