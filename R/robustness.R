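# Feature triage: test-retest reproducibility via Lin's concordance,
# redundancy pruning/clustering on the Spearman correlation matrix, and
# tumor-volume dependency with AIC/BIC functional-form selection. The robust
# set is the intersection of the three screens.

#' Lin's concordance correlation coefficient
#'
#' `LCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments. Returns `NA` (with a warning) when both vectors
#' are constant.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Concordance in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("fewer than 3 complete pairs")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  den <- vx + vy + (mx - my)^2
  if (den == 0) {
    warning("both vectors constant: LCC undefined")
    return(NA_real_)
  }
  2 * cxy / den
}

#' Test-retest reproducibility screen
#'
#' Computes per-feature Lin's concordance between paired day-1 and day-2
#' feature tables (paired by `subject_id`) and flags features with
#' `LCC >= threshold` as reproducible.
#'
#' @param day1,day2 Feature tables ([extract_feature_table()]) for the two
#'   acquisitions of the same subjects.
#' @param threshold Reproducibility threshold (default 0.7).
#' @param features Feature columns to screen; defaults to all features except
#'   the two volume entries (`tumor_volume`, `mtv`), i.e. the 129 radiomic +
#'   SUV features.
#' @return data.frame per feature: `feature`, `lcc`, `lcc_pass`.
#' @export
test_retest_screen <- function(day1, day2, threshold = 0.7,
                               features = NULL) {
  if (is.null(features)) {
    features <- setdiff(feature_columns(day1), c("tumor_volume", "mtv"))
  }
  if (!setequal(day1$subject_id, day2$subject_id)) {
    stop("day1 and day2 must contain the same subjects")
  }
  day2 <- day2[match(day1$subject_id, day2$subject_id), ]
  lcc <- vapply(features, function(f) {
    suppressWarnings(lin_ccc(day1[[f]], day2[[f]]))
  }, numeric(1))
  data.frame(feature = features, lcc = lcc,
             lcc_pass = !is.na(lcc) & lcc >= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman cross-correlation matrix with P values
#'
#' @param table Feature table.
#' @param features Feature columns (default all feature columns).
#' @return List: `rho` (symmetric, unit diagonal), `p` (large-sample t
#'   approximation, two-sided), `n`.
#' @export
spearman_matrix <- function(table, features = NULL) {
  if (is.null(features)) features <- feature_columns(table)
  X <- as.matrix(table[, features, drop = FALSE])
  n <- nrow(X)
  if (n < 5) stop("need >= 5 scans")
  rho <- suppressWarnings(stats::cor(X, method = "spearman"))
  tstat <- rho * sqrt(pmax(n - 2, 0) / pmax(1 - rho^2, 1e-300))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1 - 1e-12] <- 0
  diag(p) <- 0
  list(rho = rho, p = p, n = n)
}

#' Prune mutually correlated features
#'
#' Greedy redundancy removal: while any retained pair has
#' `rho >= rho_threshold` and `P < p_threshold`, the involved feature with
#' the lowest test-retest LCC is dropped (ties: the later feature in input
#' order). No retained pair meets both thresholds on exit; with distinct
#' LCCs the result is insensitive to input order.
#'
#' @param rho,p Matrices from [spearman_matrix()].
#' @param lcc Named per-feature LCC vector (names = feature names).
#' @param rho_threshold,p_threshold Correlation screen thresholds.
#' @return Character vector of retained feature names.
#' @export
prune_correlated <- function(rho, p, lcc, rho_threshold = 0.9,
                             p_threshold = 0.001) {
  feats <- colnames(rho)
  stopifnot(!is.null(feats), all(feats %in% names(lcc)))
  retained <- feats
  repeat {
    r <- rho[retained, retained, drop = FALSE]
    pv <- p[retained, retained, drop = FALSE]
    off <- upper.tri(r)
    bad <- off & !is.na(r) & r >= rho_threshold & pv < p_threshold
    if (!any(bad)) break
    involved <- unique(c(row(r)[bad], col(r)[bad]))
    cand <- retained[involved]
    lc <- lcc[cand]
    worst <- cand[order(lc, -match(cand, feats))][1]
    retained <- setdiff(retained, worst)
  }
  retained
}

#' Hierarchical clustering of the correlation heatmap
#'
#' Agglomerative (average linkage) clustering on distance `1 - |rho|`,
#' cut at a configurable height.
#'
#' @param rho Spearman correlation matrix.
#' @param cut_height Dendrogram cut distance (default 0.5).
#' @return List: `cluster_id` (named integer vector), `order` (dendrogram
#'   leaf order), `n_clusters`, `hclust`.
#' @export
cluster_correlations <- function(rho, cut_height = 0.5) {
  r <- rho
  r[is.na(r)] <- 0
  d <- stats::as.dist(1 - abs(r))
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  list(cluster_id = cl, order = hc$order,
       n_clusters = length(unique(cl)), hclust = hc)
}

# Gaussian least-squares AIC/BIC with k = fitted parameters + 1 (sigma).
# RSS is floored at a scale-relative tolerance so that candidate forms which
# both fit noiseless data exactly tie (and the simpler/earlier form wins).
.ls_ic <- function(rss, n, n_par, rss_floor = 1e-300) {
  rss <- max(rss, rss_floor)
  k <- n_par + 1
  list(aic = n * log(rss / n) + 2 * k, bic = n * log(rss / n) + log(n) * k)
}

#' Volume dependency of a feature
#'
#' Regresses a feature on tumor volume with four candidate functional forms
#' (`linear` a+bV, `log` a+b logV, `power` aV^b, `exponential` a e^(bV)),
#' fitted by least squares; the best form minimizes AIC (BIC reported, and
#' AIC/BIC disagreement flagged). Volume coupling is flagged from the raw
#' Spearman correlation: `rho > 0.9` with `P < 0.001`.
#'
#' @param feature Numeric feature vector.
#' @param volumes Tumor volumes (mL, > 0), same length, n >= 8.
#' @return List: `rho`, `p`, `flagged`, `best_model`, `aic`, `bic` (named
#'   vectors over candidate forms), `ic_disagree`, `coef` of the best model.
#' @export
volume_dependency <- function(feature, volumes) {
  n <- length(feature)
  if (n < 8 || length(volumes) != n) stop("need n >= 8 paired observations")
  if (any(volumes <= 0)) stop("volumes must be positive")
  ct <- suppressWarnings(stats::cor.test(feature, volumes, method = "spearman",
                                         exact = FALSE))
  rho <- unname(ct$estimate)
  pval <- ct$p.value
  if (is.na(pval) && !is.na(rho) && abs(rho) >= 1 - 1e-12) pval <- 0

  fits <- list()
  f_lin <- stats::lm(feature ~ volumes)
  fits$linear <- list(rss = sum(stats::resid(f_lin)^2), n_par = 2,
                      coef = stats::coef(f_lin))
  f_log <- stats::lm(feature ~ log(volumes))
  fits$log <- list(rss = sum(stats::resid(f_log)^2), n_par = 2,
                   coef = stats::coef(f_log))
  fits$power <- tryCatch({
    pos <- feature > 0
    st <- if (sum(pos) >= 3) {
      stats::coef(stats::lm(log(feature[pos]) ~ log(volumes[pos])))
    } else c(0, 1)
    fp <- minpack.lm::nlsLM(feature ~ a * volumes^b,
                            start = list(a = unname(exp(st[1])),
                                         b = unname(st[2])),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
    list(rss = sum(stats::resid(fp)^2), n_par = 2, coef = stats::coef(fp))
  }, error = function(e) NULL)
  fits$exponential <- tryCatch({
    pos <- feature > 0
    st <- if (sum(pos) >= 3) {
      stats::coef(stats::lm(log(feature[pos]) ~ volumes[pos]))
    } else c(0, 0)
    fe <- minpack.lm::nlsLM(feature ~ a * exp(b * volumes),
                            start = list(a = unname(exp(st[1])),
                                         b = unname(st[2])),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
    list(rss = sum(stats::resid(fe)^2), n_par = 2, coef = stats::coef(fe))
  }, error = function(e) NULL)

  fits <- fits[!vapply(fits, is.null, logical(1))]
  floor_ <- 1e-12 * sum(feature^2) / n + 1e-300
  ic <- lapply(fits, function(f) .ls_ic(f$rss, n, f$n_par, floor_))
  aic <- vapply(ic, `[[`, numeric(1), "aic")
  bic <- vapply(ic, `[[`, numeric(1), "bic")
  best <- names(aic)[which.min(aic)]
  list(rho = rho, p = pval,
       flagged = !is.na(rho) && rho > 0.9 && !is.na(pval) && pval < 0.001,
       best_model = best, aic = aic, bic = bic,
       ic_disagree = names(bic)[which.min(bic)] != best,
       coef = fits[[best]]$coef)
}

#' Run the full robustness screen
#'
#' Applies the three screens in order — test-retest reproducibility,
#' redundancy pruning, volume dependency — and intersects their pass sets.
#'
#' @param day1,day2 Test-retest feature tables.
#' @param table Scan-level feature table used for cross-correlation and
#'   volume dependency (its `tumor_volume` column supplies the volumes).
#' @param lcc_threshold,rho_threshold,p_threshold Screen thresholds.
#' @param cut_height Dendrogram cut for cluster reporting.
#' @return List of class `robustness_report`: `report` (per-feature
#'   data.frame with `lcc`, `lcc_pass`, `cluster_id`, `redundancy_dropped`,
#'   `volume_rho`, `volume_flagged`, `best_volume_model`, `robust`),
#'   `robust_features`, `n_clusters`, and the screen inputs.
#' @export
robustness_screen <- function(day1, day2, table,
                              lcc_threshold = 0.7, rho_threshold = 0.9,
                              p_threshold = 0.001, cut_height = 0.5) {
  feats <- setdiff(feature_columns(table), c("tumor_volume", "mtv"))
  tr <- test_retest_screen(day1, day2, lcc_threshold, features = feats)
  lcc <- stats::setNames(tr$lcc, tr$feature)

  sm <- spearman_matrix(table, feats)
  retained <- prune_correlated(sm$rho, sm$p, lcc, rho_threshold, p_threshold)
  cl <- cluster_correlations(sm$rho, cut_height)

  vols <- table$tumor_volume
  vd <- lapply(feats, function(f) {
    tryCatch(volume_dependency(table[[f]], vols),
             error = function(e) list(rho = NA_real_, flagged = FALSE,
                                      best_model = NA_character_))
  })
  names(vd) <- feats

  rep_df <- data.frame(
    feature = feats,
    lcc = lcc[feats],
    lcc_pass = tr$lcc_pass[match(feats, tr$feature)],
    cluster_id = cl$cluster_id[feats],
    redundancy_dropped = !(feats %in% retained),
    volume_rho = vapply(vd, function(x) x$rho %||% NA_real_, numeric(1)),
    volume_flagged = vapply(vd, function(x) isTRUE(x$flagged), logical(1)),
    best_volume_model = vapply(vd, function(x) x$best_model %||% NA_character_,
                               character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  rep_df$robust <- rep_df$lcc_pass & !rep_df$redundancy_dropped &
    !rep_df$volume_flagged
  robust <- rep_df$feature[rep_df$robust]
  if (length(robust) == 0) warning("robust feature set is empty")
  structure(list(report = rep_df, robust_features = robust,
                 n_clusters = cl$n_clusters, clustering = cl,
                 spearman = sm, n_screened = length(feats)),
            class = "robustness_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.robustness_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("<robustness_report> %d features screened\n", nrow(r)))
  cat(sprintf("  reproducible (LCC pass): %d\n", sum(r$lcc_pass, na.rm = TRUE)))
  cat(sprintf("  redundancy-dropped:      %d\n", sum(r$redundancy_dropped)))
  cat(sprintf("  volume-flagged:          %d\n", sum(r$volume_flagged)))
  cat(sprintf("  clusters:                %d\n", x$n_clusters))
  cat(sprintf("  robust set:              %d\n", length(x$robust_features)))
  invisible(x)
}
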