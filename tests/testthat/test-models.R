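test_that("confusion metrics reproduce the hand-worked binary example", {
  cm <- matrix(c(7, 3, 2, 8), 2, 2, byrow = TRUE,
               dimnames = list(c("neg", "pos"), c("neg", "pos")))
  # truth pos: TP = 8, FN = 2; truth neg: TN = 7, FP = 3
  m <- confusion_metrics(cm, positive = "pos")
  expect_equal(unname(m["sensitivity"]), 80)
  expect_equal(unname(m["specificity"]), 70)
  expect_equal(unname(m["precision"]), 100 * 8 / 11, tolerance = 1e-9)
  expect_equal(round(unname(m["precision"]), 1), 72.7)
  expect_equal(round(unname(m["npv"]), 1), 77.8)
  expect_equal(unname(m["accuracy"]), 75)
  expect_equal(round(unname(m["f_score"]), 1), 76.2)
  expect_true(all(m >= 0 & m <= 100))
})

test_that("stratified folds balance classes and respect groups", {
  y <- factor(rep(c("a", "b"), c(20, 10)))
  f <- make_folds(y, folds = 10, seed = 1)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f, y)[, "a"] == 2))
  expect_true(all(table(f, y)[, "b"] == 1))
  # determinism
  expect_identical(f, make_folds(y, folds = 10, seed = 1))
  expect_false(identical(f, make_folds(y, folds = 10, seed = 2)))
  # groups never straddle folds
  g <- rep(1:10, each = 3)
  fg <- make_folds(factor(rep("x", 30)), folds = 5, seed = 3, groups = g)
  expect_true(all(tapply(fg, g, function(v) length(unique(v))) == 1))
})

test_that("perfectly separable data scores 100% for every model", {
  set.seed(131)
  n <- 40
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- cbind(f1 = ifelse(y == "a", 0, 10) + rnorm(n, sd = 0.1),
             f2 = rnorm(n))
  for (mdl in c("cart", "svm", "nb")) {
    pr <- cross_validate(X, y, model = mdl, folds = 10, seed = 5)
    expect_equal(unname(pr$metrics["accuracy"]), 100, info = mdl)
  }
})

test_that("permuted labels give chance-level pooled accuracy", {
  set.seed(141)
  accs <- replicate(8, {
    X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("f", 1:3)))
    y <- factor(sample(rep(c("a", "b"), 20)))
    cross_validate(X, y, model = "nb", folds = 10,
                   seed = sample.int(1e6, 1))$metrics[["accuracy"]]
  })
  expect_lt(abs(mean(accs) - 50), 12)
  expect_lt(max(accs), 80)
})

test_that("cross-validation is bit-reproducible given a seed", {
  set.seed(151)
  X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- factor(rep(c("a", "b", "c"), 10))
  for (mdl in c("cart", "svm", "nb")) {
    p1 <- cross_validate(X, y, model = mdl, folds = 10, seed = 9)
    p2 <- cross_validate(X, y, model = mdl, folds = 10, seed = 9)
    expect_identical(p1$metrics, p2$metrics, info = mdl)
    expect_identical(p1$predictions, p2$predictions, info = mdl)
  }
})

test_that("pooled confusion matrix row sums equal class counts", {
  set.seed(161)
  X <- matrix(rnorm(33 * 3), 33, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- factor(rep(c("a", "b", "c"), 11))
  pr <- cross_validate(X, y, model = "cart", folds = 10, seed = 2)
  expect_equal(as.vector(rowSums(pr$confusion)), as.vector(table(y)))
  expect_equal(sum(pr$confusion), 33)
  # macro metrics well-defined for the 3-class task
  expect_true(all(is.finite(pr$metrics)))
})

test_that("identical predictors give zero improvement; planted texture wins", {
  set.seed(171)
  n <- 40
  y <- factor(rep(c("a", "b"), each = n / 2))
  tab <- data.frame(suv_mean = rnorm(n), suv_max = rnorm(n),
                    sul_peak = rnorm(n))
  tab$rs <- tab$suv_mean  # identical predictor
  out <- evaluate_predictors(tab, y, "rs", comparators = "suv_mean",
                             model = "nb", seed = 3)
  expect_true(all(abs(out$improvement) < 1e-12, na.rm = TRUE))

  # signal visible to the signature but not to any SUV column
  tab2 <- data.frame(suv_mean = rnorm(n), suv_max = rnorm(n),
                     sul_peak = rnorm(n),
                     tex = ifelse(y == "a", 0, 2) + rnorm(n, sd = 0.4))
  out2 <- evaluate_predictors(tab2, y, "tex", model = "nb", seed = 3)
  expect_gt(out2$improvement["suv_mean", "accuracy"], 0)
})
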