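test_that("Lin's concordance matches hand-computed closed forms", {
  expect_equal(lin_ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  expect_equal(lin_ccc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_warning(out <- lin_ccc(c(1, 1, 1), c(1, 1, 1)))
  expect_true(is.na(out))
})

test_that("LCC obeys Lin's inequality against Pearson on random vectors", {
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(20)
    y <- 0.5 * x + rnorm(20, sd = runif(1, 0.1, 2)) + runif(1, -2, 2)
    l <- lin_ccc(x, y)
    r <- cor(x, y)
    expect_lte(abs(l), abs(r) + 1e-12)
    expect_lte(abs(r), 1)
    expect_equal(lin_ccc(x, x), 1)
  }
})

fake_table <- function(X, ids = sprintf("S%02d", seq_len(nrow(X)))) {
  cbind(data.frame(subject_id = ids, arm = "preclinical", timepoint = "BL",
                   stringsAsFactors = FALSE),
        as.data.frame(X))
}

test_that("test-retest screen passes identical tables and rejects noise", {
  set.seed(41)
  X <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  d1 <- fake_table(X)
  scr <- test_retest_screen(d1, d1, features = paste0("f", 1:6))
  expect_true(all(scr$lcc_pass))
  expect_true(all(abs(scr$lcc - 1) < 1e-12))
  # independent day-2 noise: nothing should be reproducible at n = 40
  d2 <- fake_table(matrix(rnorm(40 * 6), 40, 6,
                          dimnames = list(NULL, paste0("f", 1:6))))
  scr2 <- test_retest_screen(d1, d2, features = paste0("f", 1:6))
  expect_equal(sum(scr2$lcc_pass), 0)
  # monotone thresholds
  scr9 <- test_retest_screen(d1, d1, threshold = 0.9,
                             features = paste0("f", 1:6))
  expect_true(all(scr9$lcc_pass <= scr$lcc_pass))
  expect_error(test_retest_screen(d1, fake_table(X, ids = rev(d1$subject_id))[1:10, ]))
})

test_that("spearman matrix is symmetric, rank-invariant, and near-zero for noise", {
  set.seed(51)
  X <- matrix(runif(100 * 3), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[, "b"] <- X[, "a"]^3  # rank-identical to a
  sm <- spearman_matrix(fake_table(X), features = c("a", "b", "c"))
  expect_equal(sm$rho, t(sm$rho))
  expect_equal(unname(diag(sm$rho)), rep(1, 3))
  expect_equal(sm$rho["a", "b"], 1)
  expect_equal(sm$p["a", "b"], 0)
  expect_lt(abs(sm$rho["a", "c"]), 0.3)
})

test_that("correlated pruning keeps the higher-LCC member of each pair", {
  # chain a~b~c with LCC a > b > c -> only a survives
  n <- 50
  feats <- c("a", "b", "c", "d")
  rho <- matrix(0.1, 4, 4, dimnames = list(feats, feats))
  diag(rho) <- 1
  rho["a", "b"] <- rho["b", "a"] <- 0.95
  rho["b", "c"] <- rho["c", "b"] <- 0.95
  p <- matrix(1, 4, 4, dimnames = list(feats, feats))
  p[rho >= 0.9] <- 0
  lcc <- c(a = 0.95, b = 0.85, c = 0.75, d = 0.5)
  kept <- prune_correlated(rho, p, lcc)
  expect_setequal(kept, c("a", "d"))
  # exact duplicates: exactly one retained
  rho2 <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  p2 <- matrix(0, 2, 2, dimnames = dimnames(rho2))
  expect_equal(prune_correlated(rho2, p2, c(x = 0.9, y = 0.8)), "x")
  # independent features survive untouched
  rho3 <- diag(3); dimnames(rho3) <- list(letters[1:3], letters[1:3])
  p3 <- matrix(1, 3, 3, dimnames = dimnames(rho3)); diag(p3) <- 0
  expect_setequal(prune_correlated(rho3, p3, c(a = 1, b = 1, c = 1)),
                  letters[1:3])
})

test_that("pruning is order-insensitive when LCCs are distinct", {
  set.seed(61)
  n_feat <- 8
  feats <- paste0("f", 1:n_feat)
  base <- matrix(rnorm(60 * 4), 60, 4)
  X <- cbind(base, base[, 1] + rnorm(60, sd = 0.01),
             base[, 2] + rnorm(60, sd = 0.01),
             matrix(rnorm(60 * 2), 60, 2))
  colnames(X) <- feats
  sm <- spearman_matrix(fake_table(X), features = feats)
  lcc <- setNames(seq(0.95, 0.6, length.out = n_feat), feats)
  kept1 <- prune_correlated(sm$rho, sm$p, lcc)
  perm <- sample(n_feat)
  kept2 <- prune_correlated(sm$rho[perm, perm], sm$p[perm, perm], lcc)
  expect_setequal(kept1, kept2)
})

test_that("correlation clustering recovers planted block structure", {
  block_rho <- function(k, size, within = 0.95) {
    n <- k * size
    m <- matrix(0, n, n)
    for (b in seq_len(k)) {
      ix <- ((b - 1) * size + 1):(b * size)
      m[ix, ix] <- within
    }
    diag(m) <- 1
    dimnames(m) <- list(paste0("f", 1:n), paste0("f", 1:n))
    m
  }
  # two perfect blocks
  cl2 <- cluster_correlations(block_rho(2, 4), cut_height = 0.5)
  expect_equal(cl2$n_clusters, 2L)
  # identity matrix -> all singletons at any cut < 1
  rho_id <- diag(5); dimnames(rho_id) <- list(paste0("f", 1:5), paste0("f", 1:5))
  expect_equal(cluster_correlations(rho_id, cut_height = 0.5)$n_clusters, 5L)
  # planted 21-block structure is recovered exactly
  cl21 <- cluster_correlations(block_rho(21, 3), cut_height = 0.5)
  expect_equal(cl21$n_clusters, 21L)
})

test_that("volume dependency flags coupled features and recovers the form", {
  set.seed(71)
  V <- runif(40, 0.2, 3)
  # exact linear coupling
  vd <- volume_dependency(2 * V, V)
  expect_equal(vd$best_model, "linear")
  expect_equal(vd$rho, 1)
  expect_true(vd$flagged)
  # quadratic power law with small noise: power form, exponent ~ 2
  f2 <- 1.5 * V^2 * exp(rnorm(40, sd = 0.02))
  vd2 <- volume_dependency(f2, V)
  expect_equal(vd2$best_model, "power")
  expect_equal(unname(vd2$coef["b"]), 2, tolerance = 0.1)
  expect_true(vd2$flagged)
  # independent feature: not flagged
  vd3 <- volume_dependency(rnorm(40), V)
  expect_false(vd3$flagged)
})

test_that("the generating form wins AIC selection on noiseless data", {
  set.seed(81)
  V <- sort(runif(30, 0.5, 4))
  gens <- list(
    linear = function(v) 1 + 2 * v,
    log = function(v) 0.5 + 1.5 * log(v),
    power = function(v) 2 * v^1.7,
    exponential = function(v) 0.8 * exp(0.9 * v)
  )
  for (form in names(gens)) {
    vd <- volume_dependency(gens[[form]](V), V)
    expect_equal(vd$best_model, form, info = form)
  }
})

test_that("robust set is the intersection of the three screens", {
  set.seed(91)
  n <- 30
  vol <- runif(n, 0.3, 2)
  tab <- fake_table(cbind(
    good = rnorm(n),            # reproducible, independent
    volcopy = 3 * vol,          # volume-coupled
    dupA = 0, dupB = 0,         # filled below: mutual duplicates
    flaky = rnorm(n)            # irreproducible
  ))
  tab$dupA <- rnorm(n); tab$dupB <- tab$dupA + rnorm(n, sd = 1e-3)
  tab$tumor_volume <- vol
  tab$mtv <- vol
  day2 <- tab
  day2$flaky <- rnorm(n)  # flaky does not reproduce
  out <- robustness_screen(tab, day2, tab)
  rep <- out$report
  expect_false(rep$robust[rep$feature == "volcopy"])
  expect_true(rep$volume_flagged[rep$feature == "volcopy"])
  expect_false(rep$robust[rep$feature == "flaky"])
  expect_false(rep$lcc_pass[rep$feature == "flaky"])
  expect_equal(sum(rep$redundancy_dropped[rep$feature %in% c("dupA", "dupB")]), 1L)
  expect_true("good" %in% out$robust_features)
  # conjunction invariant
  expect_equal(rep$robust,
               rep$lcc_pass & !rep$redundancy_dropped & !rep$volume_flagged)
  # volumes themselves are excluded from the screen
  expect_false("tumor_volume" %in% rep$feature)
  expect_equal(out$n_screened, 5L)
})
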