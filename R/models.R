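# Response classification: CART (rpart, Gini), RBF-SVM (e1071, L2-regularized
# with cost C), and Gaussian naive Bayes, evaluated by stratified k-fold
# cross-validation with fold-internal standardization and one pooled
# confusion matrix.

#' Stratified cross-validation folds
#'
#' Deterministic stratified assignment: within each class, instances are
#' shuffled by `seed` and dealt round-robin into folds. With optional
#' `groups`, whole groups are dealt instead so that rows of one group (e.g.,
#' lesions of one patient) never straddle train/test.
#'
#' @param labels Class factor.
#' @param folds Number of folds; reduced to `n` when `n < folds`.
#' @param seed Integer seed.
#' @param groups Optional grouping vector (same length as labels).
#' @return Integer fold id per instance.
#' @export
make_folds <- function(labels, folds = 10L, seed = 1L, groups = NULL) {
  y <- as.factor(labels)
  n <- length(y)
  folds <- min(folds, n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_id <- integer(n)
  if (is.null(groups)) {
    for (cl in levels(y)) {
      ix <- which(y == cl)
      ix <- ix[sample(length(ix))]
      fold_id[ix] <- rep(seq_len(folds), length.out = length(ix))
    }
  } else {
    g <- as.character(groups)
    gl <- split(seq_len(n), g)
    glab <- vapply(gl, function(ix) as.character(y[ix[1]]), character(1))
    fpos <- 0L
    for (cl in unique(glab)) {
      gs <- names(gl)[glab == cl]
      gs <- gs[sample(length(gs))]
      for (i in seq_along(gs)) {
        fold_id[gl[[gs[i]]]] <- ((fpos + i - 1L) %% folds) + 1L
      }
      fpos <- fpos + length(gs)
    }
  }
  fold_id
}

# Gaussian naive Bayes with explicit variance smoothing
# (var + smoothing, smoothing = eps * max feature variance).
gaussian_nb_fit <- function(X, y, var_smoothing = 1e-9) {
  y <- droplevels(as.factor(y))
  eps <- var_smoothing * max(apply(X, 2, stats::var), 1e-12)
  stats_by <- lapply(levels(y), function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xi)
    list(mu = mu,
         var = colMeans(sweep(Xi, 2, mu)^2) + eps,  # population variance
         prior = nrow(Xi) / nrow(X))
  })
  names(stats_by) <- levels(y)
  structure(list(classes = levels(y), stats = stats_by), class = "petrad_nb")
}

gaussian_nb_predict <- function(fit, X) {
  ll <- vapply(fit$classes, function(cl) {
    s <- fit$stats[[cl]]
    rowSums(sweep(-0.5 * sweep(sweep(X, 2, s$mu)^2, 2, s$var, "/"), 2,
                  0.5 * log(2 * pi * s$var))) + log(s$prior)
  }, numeric(nrow(X)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  factor(fit$classes[max.col(ll, ties.method = "first")],
         levels = fit$classes)
}

train_predict <- function(model, Xtr, ytr, Xte, hyper = list()) {
  ytr <- droplevels(as.factor(ytr))
  if (nlevels(ytr) < 2) {
    return(factor(rep(levels(ytr)[1], nrow(Xte)), levels = levels(ytr)))
  }
  dtr <- as.data.frame(Xtr); dte <- as.data.frame(Xte)
  names(dte) <- names(dtr)
  if (model == "cart") {
    ctrl <- rpart::rpart.control(
      minsplit = hyper$minsplit %||% 4L, minbucket = hyper$minbucket %||% 2L,
      cp = hyper$cp %||% 0, maxdepth = hyper$maxdepth %||% 30L, xval = 0)
    fit <- rpart::rpart(y ~ ., data = cbind(dtr, y = ytr), method = "class",
                        parms = list(split = "gini"), control = ctrl)
    stats::predict(fit, dte, type = "class")
  } else if (model == "svm") {
    gamma <- hyper$gamma %||% (1 / (ncol(Xtr) * max(stats::var(as.vector(Xtr)),
                                                    1e-12)))
    fit <- e1071::svm(x = as.matrix(dtr), y = ytr, kernel = "radial",
                      gamma = gamma, cost = hyper$cost %||% 1, scale = FALSE)
    stats::predict(fit, as.matrix(dte))
  } else if (model == "nb") {
    fit <- gaussian_nb_fit(as.matrix(dtr), ytr,
                           hyper$var_smoothing %||% 1e-9)
    gaussian_nb_predict(fit, as.matrix(dte))
  } else {
    stop("unknown model kind: ", model)
  }
}

#' Performance metrics from a confusion matrix
#'
#' Accuracy, F-score, sensitivity, specificity, precision, and NPV (all in
#' percent) from an integer confusion matrix (rows = truth, cols =
#' predicted). Binary tasks use `positive`; multi-class tasks macro-average
#' the one-vs-rest metrics while accuracy stays overall.
#'
#' @param cm Square confusion matrix (rows truth, columns predicted).
#' @param positive Positive class for binary tasks (default: last level).
#' @return Named numeric vector:
#'   `accuracy`, `f_score`, `sensitivity`, `specificity`, `precision`, `npv`.
#' @export
confusion_metrics <- function(cm, positive = NULL) {
  stopifnot(nrow(cm) == ncol(cm))
  classes <- rownames(cm)
  n <- sum(cm)
  acc <- 100 * sum(diag(cm)) / n
  one_vs_rest <- function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- n - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    f <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0) {
      2 * prec * sens / (prec + sens)
    } else NA_real_
    c(sens = sens, spec = spec, prec = prec, npv = npv, f = f)
  }
  if (length(classes) == 2) {
    pos <- positive %||% classes[length(classes)]
    m <- one_vs_rest(pos)
  } else {
    m <- rowMeans(vapply(classes, one_vs_rest, numeric(5)), na.rm = TRUE)
  }
  c(accuracy = acc, f_score = 100 * m[["f"]], sensitivity = 100 * m[["sens"]],
    specificity = 100 * m[["spec"]], precision = 100 * m[["prec"]],
    npv = 100 * m[["npv"]])
}

#' Cross-validated classifier performance
#'
#' Stratified k-fold cross-validation of one model: features are
#' standardized inside each training fold (the test fold reuses the training
#' centers/scales, so no leakage), out-of-fold predictions are pooled into a
#' single confusion matrix, and the six performance metrics are computed
#' from it.
#'
#' @param table Feature data.frame/matrix (instances x features).
#' @param labels Class factor.
#' @param model `"cart"`, `"svm"`, or `"nb"`.
#' @param folds Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param hyper Optional hyperparameter list (see [train_predict] defaults:
#'   CART gini/cp 0; SVM gamma `1/(d Var(X))`, cost 1; NB variance smoothing
#'   `1e-9 x max feature variance`).
#' @param positive Positive class for binary metrics.
#' @param groups Optional grouping for group-aware folds.
#' @return List of class `cv_performance`: `metrics`, `confusion`,
#'   `fold_id`, `predictions`, `model`, `seed`.
#' @export
cross_validate <- function(table, labels, model = c("nb", "svm", "cart"),
                           folds = 10L, seed = 1L, hyper = list(),
                           positive = NULL, groups = NULL) {
  model <- match.arg(model)
  X <- as.matrix(table)
  storage.mode(X) <- "double"
  y <- droplevels(as.factor(labels))
  stopifnot(nrow(X) == length(y))
  fold_id <- make_folds(y, folds, seed, groups)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sg[!is.finite(sg) | sg == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sg, "/")
    pred[te] <- train_predict(model, Xtr, y[tr], Xte, hyper)
  }
  cm <- table(truth = y, predicted = factor(pred, levels = levels(y)))
  structure(list(metrics = confusion_metrics(unclass(cm), positive),
                 confusion = cm, fold_id = fold_id, predictions = pred,
                 model = model, seed = seed),
            class = "cv_performance")
}

#' @export
print.cv_performance <- function(x, ...) {
  cat(sprintf("<cv_performance> model = %s, n = %d\n", x$model,
              sum(x$confusion)))
  print(round(x$metrics, 2))
  invisible(x)
}

#' Benchmark a radiomic signature against single-SUV predictors
#'
#' Trains the same model with the same folds on the RadSig feature set and
#' on each single-SUV comparator column, and reports per-metric percent
#' improvement `100 (RadSig - SUV) / SUV`.
#'
#' @param table Feature table containing the signature features and the
#'   comparator columns.
#' @param labels Class factor.
#' @param radsig_features Character vector (the signature features).
#' @param comparators Comparator columns
#'   (default `suv_mean`, `suv_max`, `sul_peak`).
#' @param model,folds,seed,positive,groups Passed to [cross_validate()].
#' @return List: `metrics` (predictor x metric data.frame), `improvement`
#'   (percent improvement of RadSig over each comparator; `NA` where a
#'   baseline metric is zero).
#' @export
evaluate_predictors <- function(table, labels, radsig_features,
                                comparators = c("suv_mean", "suv_max",
                                                "sul_peak"),
                                model = "nb", folds = 10L, seed = 1L,
                                positive = NULL, groups = NULL) {
  run <- function(cols) {
    cross_validate(table[, cols, drop = FALSE], labels, model = model,
                   folds = folds, seed = seed, positive = positive,
                   groups = groups)$metrics
  }
  res <- list(radsig = run(radsig_features))
  for (cmp in comparators) res[[cmp]] <- run(cmp)
  metrics <- do.call(rbind, res)
  imp <- lapply(comparators, function(cmp) {
    base <- res[[cmp]]
    ifelse(base == 0, NA_real_, 100 * (res$radsig - base) / base)
  })
  names(imp) <- comparators
  list(metrics = data.frame(predictor = rownames(metrics), metrics,
                            row.names = NULL, check.names = FALSE),
       improvement = do.call(rbind, imp))
}
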