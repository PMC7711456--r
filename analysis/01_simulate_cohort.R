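#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohorts.
#
# Two cohorts are produced: the evaluation cohort (30 patients, 2-4 slides
# each) on which every model is cross-validated, and a disjoint tile-model
# training cohort mirroring the held-out annotated training set a
# pathology-lab study would use for its tile-level networks. Both are pure
# functions of their seeds; images and masks land on disk as PNGs and the
# manifests/truth tables as CSV.

suppressPackageStartupMessages(library(histobag))

dir.create("results", showWarnings = FALSE)
dir.create("scratch/cohorts", recursive = TRUE, showWarnings = FALSE)

eval_params <- cohort_params(seed = 101L)
train_params <- cohort_params(n_patients = 10L, seed = 909L)

message("rendering evaluation cohort (seed ", eval_params$seed, ") ...")
eval_cohort <- generate_cohort(eval_params)
print(eval_cohort)
write_cohort(eval_cohort, "scratch/cohorts/eval")

message("rendering tile-training cohort (seed ", train_params$seed, ") ...")
train_cohort <- generate_cohort(train_params)
print(train_cohort)
write_cohort(train_cohort, "scratch/cohorts/train")

# cohort composition summary
comp <- as.data.frame(table(eval_cohort$manifest$label),
                      stringsAsFactors = FALSE)
names(comp) <- c("class", "n_slides")
comp$n_patients <- as.vector(table(
  eval_cohort$manifest$label[!duplicated(eval_cohort$manifest$patient_id)]))
tiles <- cohort_tiles(eval_cohort)
comp$n_tissue_tiles <- as.vector(table(tiles$index$label))
write.csv(comp, "results/01_cohort_composition.csv", row.names = FALSE)
message("evaluation cohort: ", nrow(eval_cohort$manifest), " slides, ",
        length(tiles$tiles), " tissue tiles after filtering")
print(comp)

saveRDS(list(eval = eval_cohort, train = train_cohort),
        "scratch/cohorts/cohorts.rds")
message("done; cohorts cached under scratch/cohorts/")
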