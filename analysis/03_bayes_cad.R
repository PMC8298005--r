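#!/usr/bin/env Rscript
# Stage 3: leave-one-out Bayes probability of malignancy per reading round.
#
# For each observation, the classifier is retrained on that round's own
# feature codes (the retraining that compensates for feature variation) and
# every lesion is scored by a model fitted on the other 263. Run twice:
# sonographic features alone, and features plus the patient-age term.

suppressPackageStartupMessages(library(biradsvar))

out_probs <- "results/probabilities"
dir.create(out_probs, recursive = TRUE, showWarnings = FALSE)

cohort <- read_cohort_csv("results/data/cohort.csv")

for (id in paste0("obs", 1:3)) {
  ob <- read_observation_csv(sprintf("results/data/observation_%s.csv", id))
  for (variant in c("features", "features_age")) {
    p <- loocv_posteriors(cohort, ob, alpha = 1,
                          include_age = variant == "features_age")
    path <- file.path(out_probs, sprintf("probabilities_%s_%s.csv", variant, id))
    write.csv(p, path, row.names = FALSE, quote = FALSE)
    cat(sprintf("%s / %s: median P(M|F) %.3f (malignant) vs %.3f (benign)\n",
                id, variant,
                median(p$probability_malignant[p$label == "malignant"]),
                median(p$probability_malignant[p$label == "benign"])))
  }
}
cat("Wrote leave-one-out probabilities to", out_probs, "\n")
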