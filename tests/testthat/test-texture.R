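# Every texture family is checked against an explicit-loop brute-force
# oracle on small random grids (full and partial masks), plus analytic
# degenerate cases.

toy_cases <- list(
  list(dm = c(4, 4, 4), ng = 4, seed = 101, holes = FALSE),
  list(dm = c(5, 5, 5), ng = 6, seed = 202, holes = TRUE),
  list(dm = c(4, 5, 3), ng = 3, seed = 303, holes = TRUE),
  list(dm = c(5, 4, 2), ng = 5, seed = 404, holes = FALSE)
)

make_toy <- function(case) {
  lev <- random_toy_levels(case$dm, case$ng, case$seed)
  if (case$holes) {
    set.seed(case$seed + 1)
    drop <- sample(length(lev), round(length(lev) * 0.2))
    lev[drop] <- NA
  }
  lev
}

test_that("GLCM features match the brute-force pair-counting oracle", {
  for (case in toy_cases) {
    lev <- make_toy(case)
    got <- glcm_features(toy_quantized(lev, case$ng))
    want <- bf_glcm_features(lev, case$ng)
    expect_equal(got, want[names(got)], tolerance = 1e-10)
  }
})

test_that("GLRLM features match the brute-force run-walking oracle", {
  for (case in toy_cases) {
    lev <- make_toy(case)
    got <- glrlm_features(toy_quantized(lev, case$ng))
    want <- bf_glrlm_features(lev, case$ng)
    expect_equal(got, want[names(got)], tolerance = 1e-10)
  }
})

test_that("GLSZM features match the brute-force flood-fill oracle", {
  for (case in toy_cases) {
    lev <- make_toy(case)
    got <- glszm_features(toy_quantized(lev, case$ng))
    want <- bf_glszm_features(lev, case$ng)
    expect_equal(got, want[names(got)], tolerance = 1e-10)
  }
})

test_that("GLDZM features match the brute-force border-distance oracle", {
  for (case in toy_cases) {
    lev <- make_toy(case)
    got <- gldzm_features(toy_quantized(lev, case$ng))
    want <- bf_gldzm_features(lev, case$ng)
    expect_equal(got, want[names(got)], tolerance = 1e-10)
  }
})

test_that("NGTDM features match the brute-force neighbourhood oracle", {
  for (case in toy_cases) {
    lev <- make_toy(case)
    got <- ngtdm_features(toy_quantized(lev, case$ng))
    want <- bf_ngtdm_features(lev, case$ng)
    expect_equal(got, want[names(got)], tolerance = 1e-10)
  }
})

test_that("GLDM features match the brute-force dependence oracle", {
  for (case in toy_cases) {
    lev <- make_toy(case)
    got <- gldm_features(toy_quantized(lev, case$ng))
    want <- bf_gldm_features(lev, case$ng)
    expect_equal(got, want[names(got)], tolerance = 1e-10)
  }
})

test_that("constant grid gives degenerate GLCM values", {
  lev <- array(3L, c(4, 4, 4))
  f <- glcm_features(toy_quantized(lev, 4))
  expect_equal(unname(f["glcm.joint_entropy"]), 0)
  expect_equal(unname(f["glcm.asm"]), 1)
  expect_equal(unname(f["glcm.contrast"]), 0)
  expect_equal(unname(f["glcm.joint_maximum"]), 1)
})

test_that("axial checkerboard maximizes contrast along axes", {
  # 4x4x1 checkerboard of levels 1/2: adjacent axial pairs always differ
  lev <- array(NA_integer_, c(4, 4, 1))
  for (x in 1:4) for (y in 1:4) lev[x, y, 1] <- 1L + (x + y) %% 2L
  q <- toy_quantized(lev, 2)
  # brute-force oracle on the x-direction matrix alone
  P <- bf_glcm_matrix(lev, c(1, 0, 0), 2)
  expect_equal(P[1, 1], 0)
  expect_equal(P[2, 2], 0)
  fx <- bf_glcm_features_one(P)
  expect_equal(unname(fx["contrast"]), 1)       # |1-2|^2 on every pair
  expect_lte(unname(fx["correlation"]), 0)      # anticorrelated neighbours
  f <- glcm_features(q)
  expect_equal(got <- unname(f["glcm.contrast"]),
               unname(bf_glcm_features(lev, 2)["glcm.contrast"]))
})

test_that("texture matrices are normalized distributions", {
  lev <- random_toy_levels(c(5, 5, 5), 5, 77)
  q <- toy_quantized(lev, 5)
  for (r in seq_len(nrow(bf_dirs))) {
    P <- bf_glcm_matrix(lev, bf_dirs[r, ], 5)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
})

test_that("single-voxel mask fails GLCM cleanly", {
  lev <- array(NA_integer_, c(3, 3, 3))
  lev[2, 2, 2] <- 1L
  expect_error(glcm_features(toy_quantized(lev, 2)))
})

test_that("higher-order features are invariant to monotone intensity maps", {
  set.seed(5)
  img <- array(rlnorm(7^3, 0, 0.5), c(7, 7, 7))
  msk <- array(TRUE, dim(img))
  q1 <- equalize_quantize(img, msk, 8)
  q2 <- equalize_quantize(exp(img), msk, 8)  # strictly monotone
  expect_identical(q1$levels, q2$levels)
  expect_equal(glcm_features(q1), glcm_features(q2))
  expect_equal(glszm_features(q1), glszm_features(q2))
  expect_equal(ngtdm_features(q1), ngtdm_features(q2))
})
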