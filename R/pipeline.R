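# End-to-end synthetic co-clinical pipeline: test-retest simulation and
# screen -> longitudinal cohort -> extraction -> robustness -> ReliefF ->
# RadSig -> cross-validated models benchmarked against SUV metrics.

#' Run the full synthetic co-clinical analysis pipeline
#'
#' Simulates a test-retest cohort and a longitudinal therapy cohort under
#' one [phantom_config()], extracts the 131-feature panel from every scan,
#' runs the three-part robustness screen, ranks the robust features with
#' ReliefF per task (prediction: baseline features; assessment:
#' on-treatment minus baseline differences), assembles the two signatures,
#' and cross-validates CART/SVM/NB on each signature against the SUV
#' comparators.
#'
#' All stages are pure functions of `(config, seeds)`: rerunning with the
#' same arguments reproduces every number bit-exactly.
#'
#' @param config A [phantom_config()]; its `seed` drives all simulation.
#' @param n_retest Number of test-retest pairs (default 40).
#' @param lcc_threshold,rho_threshold,p_threshold,cut_height Screen
#'   thresholds (defaults 0.7 / 0.9 / 0.001 / 0.5).
#' @param tau ReliefF relevance threshold (default 0.05).
#' @param radsig_size Signature size (default 4).
#' @param folds,cv_seed Cross-validation settings.
#' @param models Model kinds to evaluate.
#' @param out_dir Optional directory: when given, feature tables, the
#'   robustness report, weights, signatures, and performance tables are
#'   written there as CSV/JSON.
#' @return List with `retest` (tables + screen), `cohort`, `screen`,
#'   `prediction` and `assessment` task results (weights, shortlist,
#'   radsig, performance per model, SUV comparison), and `config`.
#' @export
run_pipeline <- function(config = phantom_config(),
                         n_retest = 40L,
                         lcc_threshold = 0.7, rho_threshold = 0.9,
                         p_threshold = 0.001, cut_height = 0.5,
                         tau = 0.05, radsig_size = 4L,
                         folds = 10L, cv_seed = 7L,
                         models = c("cart", "svm", "nb"),
                         out_dir = NULL) {
  retest_cfg <- config
  pairs <- lapply(seq_len(n_retest), function(i) {
    generate_test_retest_pair(retest_cfg, sprintf("R%03d", i))
  })
  day1 <- extract_feature_table(lapply(pairs, `[[`, "day1"))
  day2 <- extract_feature_table(lapply(pairs, `[[`, "day2"))

  cohort <- generate_longitudinal_cohort(config)
  feat <- extract_feature_table(cohort$scans)
  bl <- feat[feat$timepoint == "BL", ]
  screen <- robustness_screen(day1, day2, bl,
                              lcc_threshold = lcc_threshold,
                              rho_threshold = rho_threshold,
                              p_threshold = p_threshold,
                              cut_height = cut_height)
  robust <- screen$robust_features
  if (length(robust) < radsig_size) {
    warning("robust set smaller than signature size; using LCC ranking")
    robust <- screen$report$feature[order(-screen$report$lcc)][
      seq_len(max(radsig_size, 8L))]
  }

  labels <- cohort$labels
  run_task <- function(task_table, task) {
    ord <- match(labels$subject_id, task_table$subject_id)
    X <- task_table[ord, robust, drop = FALSE]
    w <- relieff_rank(X, labels$class)
    shortlist <- rank_importance(w, tau = tau)
    rs_pool <- if (length(shortlist) > 0) shortlist else sort(w, decreasing = TRUE)
    rs <- build_radsig(rs_pool, size = radsig_size, task = task)
    perf <- lapply(models, function(m) {
      cross_validate(X[, rs$features, drop = FALSE], labels$class,
                     model = m, folds = folds, seed = cv_seed)
    })
    names(perf) <- models
    cmp_table <- cbind(X, task_table[ord, c("suv_mean", "suv_max", "sul_peak")])
    comparison <- evaluate_predictors(cmp_table, labels$class, rs$features,
                                      model = "nb", folds = folds,
                                      seed = cv_seed)
    list(weights = w, shortlist = shortlist, radsig = rs,
         performance = perf, comparison = comparison)
  }
  prediction <- run_task(bl, "prediction")
  assessment <- run_task(delta_feature_table(feat), "assessment")

  result <- list(config = config,
                 retest = list(day1 = day1, day2 = day2),
                 cohort = list(features = feat, labels = labels),
                 screen = screen,
                 prediction = prediction, assessment = assessment)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(feat, file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(screen$report, file.path(out_dir, "robustness_report.csv"),
                     row.names = FALSE)
    for (task in c("prediction", "assessment")) {
      tk <- result[[task]]
      utils::write.csv(
        data.frame(feature = names(tk$weights), weight = tk$weights),
        file.path(out_dir, paste0("relieff_", task, ".csv")),
        row.names = FALSE)
      jsonlite::write_json(
        list(task = task, features = tk$radsig$features,
             weights = tk$radsig$weights),
        file.path(out_dir, paste0("radsig_", task, ".json")),
        auto_unbox = TRUE, digits = NA)
      perf <- do.call(rbind, lapply(names(tk$performance), function(m) {
        data.frame(model = m, t(tk$performance[[m]]$metrics))
      }))
      utils::write.csv(perf, file.path(out_dir, paste0("performance_", task,
                                                       ".csv")),
                       row.names = FALSE)
    }
  }
  result
}
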