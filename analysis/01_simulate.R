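#!/usr/bin/env Rscript
# Step 1 — simulate the study inputs.
#
# Two kinds of synthetic input are produced:
#   (a) quiescent and activated PBMC feature cohorts drawn directly from the
#       cell-type profiles (fast path for the statistical analyses), at the
#       per-type cell counts of the imaging cohort;
#   (b) one ground-truthed two-channel FLIM field of view, exported as
#       multi-page TIFF decay cubes + label mask + truth CSV, for the
#       image-processing steps 02-03.

suppressPackageStartupMessages(library(omiflim))
dir.create("results", showWarnings = FALSE)
SEED <- 20260101L

q_counts <- c(helper_T = 553, cytotoxic_T = 554, monocyte = 425,
              B = 368, NK = 510)
a_counts <- c(helper_T = 363, cytotoxic_T = 353, monocyte = 305,
              B = 340, NK = 267)

cohort <- function(condition, counts, off) {
  profs <- default_pbmc_profiles(condition)
  names(profs) <- vapply(profs, `[[`, character(1), "name")
  do.call(rbind, lapply(seq_along(counts), function(i) {
    sample_feature_table(profs[names(counts)[i]], counts[[i]],
                         rng_seed = SEED + off + i, condition = condition)
  }))
}

quiescent <- cohort("quiescent", q_counts, 0L)
activated <- cohort("activated", a_counts, 100L)
write_feature_csv(quiescent, "results/cohort_quiescent.csv")
write_feature_csv(activated, "results/cohort_activated.csv")
cat(sprintf("cohorts: %d quiescent + %d activated cells -> results/cohort_*.csv\n",
            nrow(quiescent), nrow(activated)))

# a compact 30-cell field of view, helper T vs monocyte
profs <- default_pbmc_profiles("quiescent")
names(profs) <- vapply(profs, `[[`, character(1), "name")
sel <- profs[c("helper_T", "monocyte")]
sel[[1]]$abundance <- 0.5; sel[[2]]$abundance <- 0.5
scene <- build_scene(sel, field_size = c(220, 220), n_cells = 30,
                     rng_seed = SEED)
write_scene(scene, "results/scene")
cat(sprintf("scene: %d cells on a %d x %d field -> results/scene/\n",
            nrow(scene$truth_table), nrow(scene$label_image),
            ncol(scene$label_image)))
print(table(scene$truth_table$cell_type))
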