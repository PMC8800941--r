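#!/usr/bin/env Rscript
# Rank robust features with ReliefF for the two tasks (prediction: baseline
# features; assessment: on-treatment minus baseline differences), assemble
# the 4-feature radiomic signatures, and trace accuracy versus number of
# ranked features for CART / SVM / NB. Writes results/radsig/.

suppressPackageStartupMessages(library(petrad))

feat <- utils::read.csv("results/features/longitudinal.csv", check.names = FALSE)
labels <- utils::read.csv("results/cohorts/labels.csv")
labels$class <- factor(labels$class,
                       levels = c("response", "partial", "no_response"))
robust <- jsonlite::read_json("results/robustness/summary.json",
                              simplifyVector = TRUE)$robust_features

bl <- feat[feat$timepoint == "BL", ]
dl <- delta_feature_table(feat)
dir.create("results/radsig", showWarnings = FALSE, recursive = TRUE)

for (task in c("prediction", "assessment")) {
  tab <- if (task == "prediction") bl else dl
  ord <- match(labels$subject_id, tab$subject_id)
  X <- tab[ord, robust, drop = FALSE]
  w <- suppressWarnings(relieff_rank(X, labels$class))
  shortlist <- rank_importance(w, tau = 0.05, top_n = 15)
  rs <- build_radsig(shortlist, size = 4, task = task)
  print(rs)
  utils::write.csv(data.frame(feature = names(w), weight = w),
                   sprintf("results/radsig/relieff_%s.csv", task),
                   row.names = FALSE)
  jsonlite::write_json(list(task = task, features = rs$features,
                            weights = rs$weights),
                       sprintf("results/radsig/radsig_%s.json", task),
                       auto_unbox = TRUE, digits = NA)
  ranked <- names(sort(w, decreasing = TRUE))
  curve <- accuracy_vs_feature_count(X, labels$class, ranked,
                                     max_n = min(10, length(ranked)),
                                     folds = 10, seed = 7)
  utils::write.csv(curve$curve,
                   sprintf("results/radsig/accuracy_curve_%s.csv", task),
                   row.names = FALSE)
  message(task, " saturation points: ",
          paste(names(curve$saturation), curve$saturation,
                sep = "=", collapse = ", "))
}
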