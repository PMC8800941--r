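small_cfg <- function(...) {
  # compact tumors keep the test grids small
  phantom_config(tumor_radius_range_mm = c(3, 4.5), n_subjects = 6,
                 seed = 11, ...)
}

test_that("identical config and seed give bit-identical scans", {
  s1 <- generate_scan(small_cfg(), "S1")
  s2 <- generate_scan(small_cfg(), "S1")
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  # different subject -> different tumor
  s3 <- generate_scan(small_cfg(), "S2")
  expect_false(identical(s1$image, s3$image))
})

test_that("zero noise and zero texture give a uniform tumor", {
  cfg <- small_cfg(noise_sd = 0, texture_amplitude = 0)
  s <- suv_image(generate_scan(cfg, "S1"))
  v <- s$image[s$mask]
  expect_equal(var(v), 0)
  expect_equal(unique(v), cfg$tumor_suv_mean)
})

test_that("voxelized sphere volume approximates the analytic volume", {
  cfg <- phantom_config(tumor_radius_range_mm = c(5, 5), voxel_spacing_mm = 1,
                        seed = 2)
  s <- generate_scan(cfg, "S1", axes_mm = 5)
  expect_lt(abs(sum(s$mask) - 4 / 3 * pi * 5^3) / (4 / 3 * pi * 5^3), 0.10)
})

test_that("oversized tumors fail explicitly", {
  expect_error(generate_scan(small_cfg(), "S1", axes_mm = 50),
               "field of view")
})

test_that("SUV normalization is exercised end-to-end by phantom metadata", {
  cfg <- small_cfg(noise_sd = 0, texture_amplitude = 0)
  s <- generate_scan(cfg, "S1")
  expect_equal(s$units, "Bq/mL")
  suv <- suv_image(s)
  expect_equal(mean(suv$image[suv$mask]), cfg$tumor_suv_mean, tolerance = 1e-9)
})

test_that("zero retest jitter reproduces day 1 exactly", {
  pr <- generate_test_retest_pair(small_cfg(retest_jitter = 0), "S1")
  expect_identical(pr$day1$image, pr$day2$image)
  expect_identical(pr$day1$mask, pr$day2$mask)
})

test_that("positive jitter perturbs day 2 but keeps the same tumor", {
  pr <- generate_test_retest_pair(small_cfg(retest_jitter = 0.1), "S1")
  expect_false(identical(pr$day1$image, pr$day2$image))
  # same underlying tumor: volumes within a few voxel layers
  expect_lt(abs(sum(pr$day1$mask) - sum(pr$day2$mask)) / sum(pr$day1$mask),
            0.15)
})

test_that("increasing jitter does not improve mean feature reproducibility", {
  lcc_at <- function(j) {
    cfg <- phantom_config(tumor_radius_range_mm = c(3, 4.5), n_subjects = 8,
                          retest_jitter = j, seed = 5)
    pairs <- lapply(1:8, function(i) {
      generate_test_retest_pair(cfg, sprintf("R%02d", i))
    })
    d1 <- extract_feature_table(lapply(pairs, `[[`, "day1"), ng = 32)
    d2 <- extract_feature_table(lapply(pairs, `[[`, "day2"), ng = 32)
    mean(test_retest_screen(d1, d2)$lcc, na.rm = TRUE)
  }
  l0 <- lcc_at(0)
  l_small <- lcc_at(0.05)
  l_large <- lcc_at(0.5)
  expect_equal(l0, 1)
  expect_lte(l_small + 1e-9, l0)
  expect_lt(l_large, l_small)
})

test_that("longitudinal cohort honours class design and volume dynamics", {
  cfg <- phantom_config(tumor_radius_range_mm = c(3, 4.5), n_subjects = 30,
                        responder_fraction = 0.5, seed = 9)
  ch <- generate_longitudinal_cohort(cfg)
  expect_equal(sum(ch$labels$class == "response"), 15)
  expect_equal(length(ch$scans), 60)
  # volume-change percentages match the assigned class
  lab <- classify_preclinical_response(ch$labels$volume_change_pct)
  expect_equal(as.character(lab), as.character(ch$labels$class))
  # rendered masks follow the latent dynamics: responders shrink
  ids <- ch$labels$subject_id[ch$labels$class == "response"][1:3]
  for (sid in ids) {
    bl <- Filter(function(s) s$subject_id == sid && s$timepoint == "BL",
                 ch$scans)[[1]]
    tx <- Filter(function(s) s$subject_id == sid && s$timepoint == "ONTX",
                 ch$scans)[[1]]
    expect_lt(sum(tx$mask), sum(bl$mask))
  }
})

test_that("feature-space cohort plants the requested signal", {
  sim <- simulate_feature_table(n = 40, n_signal = 3, n_noise = 5,
                                effect = 3, seed = 21)
  expect_equal(dim(sim$table), c(40L, 8L))
  expect_equal(length(sim$signal_names), 3L)
  mu_diff <- abs(colMeans(sim$table[sim$labels == "C1", ]) -
                   colMeans(sim$table[sim$labels == "C2", ]))
  expect_true(all(mu_diff[sim$signal_names] > 1.5))
  expect_true(all(mu_diff[setdiff(names(sim$table), sim$signal_names)] < 1.5))
})

test_that("NIfTI cohort round-trip preserves scans and metadata", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg()
  scans <- list(generate_scan(cfg, "S1"), generate_scan(cfg, "S2"))
  write_cohort_nifti(scans, dir)
  back <- read_cohort_nifti(dir)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$subject_id, "S1")
  expect_equal(back[[1]]$image, scans[[1]]$image, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back[[1]]$spacing_mm, scans[[1]]$spacing_mm, tolerance = 1e-6)
  expect_equal(sum(back[[2]]$mask), sum(scans[[2]]$mask))
})
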