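# ReliefF relevance ranking and radiomic-signature (RadSig) assembly.
# Multi-class ReliefF with Kononenko prior-weighted misses, Manhattan
# distance on min-max scaled features, and a deterministic full pass over
# all instances (k = 10 neighbours by default).

#' ReliefF feature weights
#'
#' For each instance, the k nearest same-class hits and, per other class,
#' the k nearest misses (Manhattan distance on min-max scaled features)
#' update each feature weight by the prior-weighted mean miss difference
#' minus the mean hit difference, `diff(f, a, b) = |a_f - b_f| / range(f)`.
#' Accumulated updates are normalized by the number of sampled instances, so
#' weights lie in `[-1, 1]`. A full deterministic pass over all instances is
#' used unless `n_sample` is given; distance ties break by instance index.
#' Classes with fewer than `k + 1` members use the available neighbours
#' (with a warning).
#'
#' @param table Feature data.frame or matrix (instances x features).
#' @param labels Factor of class labels (>= 2 classes).
#' @param k Neighbours per class (default 10).
#' @param n_sample Number of sampled instances, or `NULL` for all.
#' @param seed Seed used only when subsampling.
#' @return Named numeric vector of feature weights.
#' @export
relieff_rank <- function(table, labels, k = 10L, n_sample = NULL, seed = 1L) {
  X <- as.matrix(table)
  storage.mode(X) <- "double"
  y <- as.factor(labels)
  n <- nrow(X)
  stopifnot(length(y) == n, nlevels(droplevels(y)) >= 2)
  y <- droplevels(y)

  rng <- apply(X, 2, function(v) diff(range(v)))
  scl <- ifelse(rng > 0, rng, 1)
  Xs <- sweep(sweep(X, 2, apply(X, 2, min)), 2, scl, "/")
  Xs[, rng == 0] <- 0

  priors <- table(y) / n
  idx <- seq_len(n)
  if (!is.null(n_sample) && n_sample < n) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    idx <- sort(sample(n, n_sample))
  }
  m <- length(idx)
  D <- as.matrix(stats::dist(Xs, method = "manhattan"))
  W <- numeric(ncol(X))
  warned <- FALSE
  for (i in idx) {
    ci <- y[i]
    hit_pool <- which(y == ci & seq_len(n) != i)
    if (length(hit_pool) == 0) next
    kh <- min(k, length(hit_pool))
    if (kh < k && !warned) {
      warning("some classes have <= k members; using fewer neighbours")
      warned <- TRUE
    }
    hits <- hit_pool[order(D[i, hit_pool], hit_pool)][seq_len(kh)]
    W <- W - colMeans(abs(Xs[hits, , drop = FALSE] -
                            rep(Xs[i, ], each = kh))) / m
    for (cl in levels(y)[levels(y) != ci]) {
      miss_pool <- which(y == cl)
      if (length(miss_pool) == 0) next
      km <- min(k, length(miss_pool))
      miss <- miss_pool[order(D[i, miss_pool], miss_pool)][seq_len(km)]
      wcl <- priors[[cl]] / (1 - priors[[ci]])
      W <- W + wcl * colMeans(abs(Xs[miss, , drop = FALSE] -
                                    rep(Xs[i, ], each = km))) / m
    }
  }
  stats::setNames(W, colnames(X))
}

#' Shortlist features by ReliefF weight
#'
#' Features with weight above the relevance threshold `tau`, sorted by
#' decreasing weight (ties keep input order) and truncated at `top_n`.
#'
#' @param weights Named weight vector from [relieff_rank()].
#' @param tau Relevance threshold (default 0.05).
#' @param top_n Shortlist cap (default 15).
#' @return Named weight vector of the shortlist (possibly empty).
#' @export
rank_importance <- function(weights, tau = 0.05, top_n = 15L) {
  keep <- which(weights > tau)
  if (length(keep) == 0) {
    warning("no feature weight exceeds tau")
    return(weights[0])
  }
  ord <- keep[order(-weights[keep], keep)]
  weights[ord[seq_len(min(top_n, length(ord)))]]
}

#' Assemble a radiomic signature (RadSig)
#'
#' The top `size` shortlisted features for one task. If the shortlist is
#' shorter than `size`, all of it is used and the result flagged.
#'
#' @param shortlist Named weight vector from [rank_importance()].
#' @param size Signature size (default 4).
#' @param task `"prediction"` (BL features) or `"assessment"` (delta
#'   features).
#' @return Object of class `radsig`: list with `task`, `features`,
#'   `weights`, `truncated`.
#' @export
build_radsig <- function(shortlist, size = 4L,
                         task = c("prediction", "assessment")) {
  task <- match.arg(task)
  truncated <- length(shortlist) < size
  if (truncated) warning("shortlist shorter than requested signature size")
  take <- seq_len(min(size, length(shortlist)))
  structure(list(task = task, features = names(shortlist)[take],
                 weights = unname(shortlist[take]), truncated = truncated),
            class = "radsig")
}

#' @export
print.radsig <- function(x, ...) {
  cat(sprintf("<radsig> task = %s\n", x$task))
  for (i in seq_along(x$features)) {
    cat(sprintf("  %d. %-28s w = %.4f\n", i, x$features[i], x$weights[i]))
  }
  invisible(x)
}

#' Cross-validated accuracy versus number of ranked features
#'
#' Re-runs cross-validation with the top 1..`max_n` ranked features for each
#' model and reports the accuracy curve plus the saturation point (the
#' smallest count whose accuracy is within `sat_tol` accuracy points of the
#' curve maximum).
#'
#' @param table Feature table (data.frame).
#' @param labels Class factor.
#' @param ranked Character vector of features in decreasing relevance.
#' @param models Model kinds (subset of `"cart"`, `"svm"`, `"nb"`).
#' @param max_n Largest feature count to evaluate.
#' @param folds,seed Cross-validation settings.
#' @param sat_tol Accuracy-point tolerance defining saturation (default 1).
#' @return List: `curve` (data.frame model x n_features x accuracy),
#'   `saturation` (named vector per model).
#' @export
accuracy_vs_feature_count <- function(table, labels, ranked,
                                      models = c("cart", "svm", "nb"),
                                      max_n = length(ranked), folds = 10L,
                                      seed = 1L, sat_tol = 1) {
  max_n <- min(max_n, length(ranked))
  rows <- list()
  for (mdl in models) {
    for (nf in seq_len(max_n)) {
      pr <- cross_validate(table[, ranked[seq_len(nf)], drop = FALSE],
                           labels, model = mdl, folds = folds, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(model = mdl, n_features = nf,
                                              accuracy = pr$metrics[["accuracy"]])
    }
  }
  curve <- do.call(rbind, rows)
  sat <- vapply(models, function(mdl) {
    acc <- curve$accuracy[curve$model == mdl]
    min(which(acc >= max(acc) - sat_tol))
  }, numeric(1))
  list(curve = curve, saturation = sat)
}
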