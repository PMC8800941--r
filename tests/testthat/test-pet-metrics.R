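test_that("SUV normalization follows the dose/weight relation and is linear", {
  expect_equal(normalize_suv(1000, 25, 7.4e6), 1000 * 25 / 7.4e6,
               tolerance = 1e-12)
  expect_equal(normalize_suv(1000, 25, 7.4e6), 0.003378, tolerance = 1e-3)
  # activity = dose/weight everywhere -> SUV = 1
  expect_equal(normalize_suv(7.4e6 / 25, 25, 7.4e6), 1)
  # linear in weight and activity
  a <- array(runif(27, 100, 2000), c(3, 3, 3))
  expect_equal(normalize_suv(a, 50, 7.4e6), 2 * normalize_suv(a, 25, 7.4e6))
  expect_equal(normalize_suv(2 * a, 25, 7.4e6), 2 * normalize_suv(a, 25, 7.4e6))
  expect_error(normalize_suv(a, 0, 7.4e6))
  expect_error(normalize_suv(a, 25, -1))
})

test_that("suv_summary reports order statistics and volumes correctly", {
  img <- array(3, c(10, 10, 10))
  s <- make_suv_record(img)
  sm <- suv_summary(s)
  expect_equal(sm$suv_mean, 3)
  expect_equal(sm$suv_max, 3)
  expect_equal(sm$suv_sd, 0)
  # uniform tumor: MTV = tumor volume, TLG = mean * MTV
  expect_equal(sm$mtv, sm$tumor_volume)
  expect_equal(sm$tlg, 3 * sm$mtv)
  # 1000 voxels at 1 mm^3 -> 1.0 mL
  expect_equal(sm$tumor_volume, 1.0)

  # single hot voxel: max/median order statistics
  img2 <- array(1, c(10, 10, 10))
  img2[5, 5, 5] <- 10
  sm2 <- suv_summary(make_suv_record(img2))
  expect_equal(sm2$suv_max, 10)
  expect_equal(sm2$suv_median, 1)
  expect_lt(sm2$sul_peak, sm2$suv_max)  # sphere averaging is strict here
  expect_true(sm2$suv_min <= sm2$suv_median &&
                sm2$suv_median <= sm2$suv_max)
  expect_true(sm2$suv_mean >= sm2$suv_min && sm2$suv_mean <= sm2$suv_max)
})

test_that("SUL peak falls back to the VOI mean for sub-sphere tumors", {
  img <- array(2, c(5, 5, 5))
  mask <- array(FALSE, c(5, 5, 5))
  mask[2:4, 2:4, 2:4] <- TRUE  # 27 mm^3 << 1 mL
  pk <- suv_peak(make_suv_record(img, mask))
  expect_true(pk$peak_fallback)
  expect_equal(pk$suv_peak, 2)
  # uniform tumor with LBM == weight (preclinical SUL == SUV)
  expect_equal(pk$sul_peak, 2)
})

test_that("clinical SUL uses Janmahasatian lean body mass", {
  lbm <- lean_body_mass_kg("F", 70, 165)
  bmi <- 70 / 1.65^2
  expect_equal(lbm, 9270 * 70 / (8780 + 244 * bmi))
  expect_lt(lbm, 70)
  lbm_m <- lean_body_mass_kg("M", 70, 165)
  expect_equal(lbm_m, 9270 * 70 / (6680 + 216 * bmi))

  img <- array(4, c(40, 40, 40))  # 2 mm spacing -> 512 mL VOI
  s <- scan_record("C1", img, array(TRUE, dim(img)), 2, arm = "clinical",
                   units = "SUV", injected_dose_bq = 3.7e8,
                   body_weight_g = 70000, sex = "F", height_cm = 165)
  pk <- suv_peak(s)
  expect_false(pk$peak_fallback)
  expect_equal(pk$sul_peak, pk$suv_peak * lbm / 70, tolerance = 1e-9)
})

test_that("metabolic tumor volume thresholds at a fraction of SUVmax", {
  img <- array(1, c(10, 10, 10))
  img[, , 1:5] <- 10  # half the voxels hot
  s <- make_suv_record(img)
  expect_equal(metabolic_tumor_volume(s, 0.40), 0.5)  # half of 1 mL
  expect_equal(metabolic_tumor_volume(s, 0), 1.0)
  expect_equal(metabolic_tumor_volume(s, 0.05), 1.0)  # 1 >= 0.5
})

test_that("caliper volume matches the printed 1/6 L W^2 formula", {
  expect_equal(caliper_volume(6, 3), 9)
  expect_equal(caliper_volume(10, 5), 1 / 6 * 10 * 25)
  expect_equal(round(caliper_volume(10, 5), 2), 41.67)
  expect_equal(caliper_volume(0, 0), 0)
  expect_equal(caliper_volume(10, 0), 0)
  expect_equal(caliper_volume(10, 5, ellipsoid = TRUE), pi / 6 * 10 * 25)
  expect_error(caliper_volume(-1, 1))
})

test_that("percent change and response trichotomy partition the line", {
  expect_equal(percent_change(10, 5), -50)
  expect_equal(percent_change(4, 4), 0)
  expect_error(percent_change(0, 5))

  expect_equal(as.character(classify_preclinical_response(-25)), "response")
  expect_equal(as.character(classify_preclinical_response(0)), "partial")
  expect_equal(as.character(classify_preclinical_response(-20)), "partial")
  expect_equal(as.character(classify_preclinical_response(20)), "partial")
  expect_equal(as.character(classify_preclinical_response(20.01)), "no_response")
  # every input gets exactly one label
  x <- seq(-100, 100, by = 0.5)
  labs <- classify_preclinical_response(x)
  expect_false(any(is.na(labs)))
  expect_equal(sum(labs == "partial"), sum(abs(x) <= 20))
})
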