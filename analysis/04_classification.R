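#!/usr/bin/env Rscript
# Stage 4 — train and evaluate the five classifiers.
#
# Plant-wise 70/30 split (no plant's ROIs straddle the sets), SNV-smoothed
# ROI mean spectra as features, the five algorithms at their published
# hyperparameters, and the full evaluation surface per algorithm. Also runs
# the plant-grouped 5-fold cross-validation on the training ROIs for the
# random forest as a stability check.

library(weedspec)

seed <- 1
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(roi_counts = weed_roi_counts(), seed = seed)
feats <- roi_features(cohort)
plan <- plant_wise_split(cohort, train_fraction = 0.7, seed = seed + 1)
write_split_plan(plan, "results/split_plan.tsv")
role <- setNames(plan$role, plan$plant_id)[feats$plant]
tr <- role == "train"
cat("training ROIs:", sum(tr), " test ROIs:", sum(!tr), "\n")

reports <- list()
for (algo in c("rf", "svm", "nn", "maxent", "simca")) {
  m <- train_classifier(feats$x[tr, ], algo, y = feats$y[tr],
                        seed = seed + 2)
  prob <- predict(m, feats$x[!tr, ], type = "prob")
  rep <- evaluation_report(feats$y[!tr], prob, priors = m$priors,
                           algorithm = algo)
  reports[[algo]] <- rep
  write.table(rep$per_class, sprintf("results/report_%s.tsv", algo),
              sep = "\t", quote = FALSE, row.names = FALSE)
  print(rep)
}

comparison <- compare_report(reports)
write.table(comparison, "results/comparison.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nranking by test accuracy:\n")
print(comparison, digits = 3, row.names = FALSE)

fm_train <- structure(list(x = feats$x[tr, ], y = droplevels(feats$y[tr]),
                           plant = feats$plant[tr],
                           wavelengths = feats$wavelengths),
                      class = "feature_matrix")
cv <- cross_validate(fm_train, "rf", folds = 5, seed = seed + 3)
cat(sprintf("\nrandom-forest 5-fold CV accuracy on training ROIs: %.3f\n",
            mean(cv$fold_scores)))
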