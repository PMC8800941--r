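#!/usr/bin/env Rscript
# Benchmark the 4-feature signatures: 10-fold cross-validated CART / SVM /
# NB performance per task, and percent improvement of NB-RadSig over the
# SUVmean / SUVmax / SULpeak single-metric predictors. Writes
# results/models/.

suppressPackageStartupMessages(library(petrad))

feat <- utils::read.csv("results/features/longitudinal.csv", check.names = FALSE)
labels <- utils::read.csv("results/cohorts/labels.csv")
labels$class <- factor(labels$class,
                       levels = c("response", "partial", "no_response"))
bl <- feat[feat$timepoint == "BL", ]
dl <- delta_feature_table(feat)
dir.create("results/models", showWarnings = FALSE, recursive = TRUE)

for (task in c("prediction", "assessment")) {
  tab <- if (task == "prediction") bl else dl
  ord <- match(labels$subject_id, tab$subject_id)
  rs <- jsonlite::read_json(sprintf("results/radsig/radsig_%s.json", task),
                            simplifyVector = TRUE)
  X <- tab[ord, rs$features, drop = FALSE]
  perf <- do.call(rbind, lapply(c("cart", "svm", "nb"), function(m) {
    pr <- cross_validate(X, labels$class, model = m, folds = 10, seed = 7)
    data.frame(task = task, model = m, t(pr$metrics))
  }))
  print(perf, digits = 4)
  utils::write.csv(perf, sprintf("results/models/performance_%s.csv", task),
                   row.names = FALSE)

  cmp_tab <- cbind(X, tab[ord, c("suv_mean", "suv_max", "sul_peak")])
  cmp <- evaluate_predictors(cmp_tab, labels$class, rs$features,
                             model = "nb", folds = 10, seed = 7)
  utils::write.csv(cmp$metrics,
                   sprintf("results/models/comparison_%s.csv", task),
                   row.names = FALSE)
  utils::write.csv(data.frame(baseline = rownames(cmp$improvement),
                              cmp$improvement, check.names = FALSE),
                   sprintf("results/models/improvement_%s.csv", task),
                   row.names = FALSE)
  message(task, ": NB-RadSig accuracy improvement over SUVmean = ",
          round(cmp$improvement["suv_mean", "accuracy"], 1), "%")
}
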