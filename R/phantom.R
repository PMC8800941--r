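# Digital phantom cohorts: textured ellipsoidal tumors on a noisy background,
# at preclinical (~0.8 mm) or clinical (~2 mm) voxel sizes, with paired
# test-retest acquisitions and baseline/on-treatment pairs whose latent
# responder status drives volume and heterogeneity dynamics. Every scan is a
# pure function of (config, subject_id, timepoint), so identical configs and
# seeds give bit-identical cohorts.

#' Phantom cohort configuration
#'
#' Defines the study conditions a synthetic co-clinical cohort is generated
#' under. The texture inside each tumor is a correlated Gaussian random
#' field (white noise smoothed with a Gaussian kernel whose width is the
#' correlation length), scaled by `texture_amplitude` relative to the tumor
#' mean; voxel noise is added on top and intensities are clipped at zero.
#'
#' @param arm `"preclinical"` or `"clinical"`; arms differ only in voxel
#'   spacing, tumor size range, and dose/weight metadata scale.
#' @param n_subjects Cohort size.
#' @param voxel_spacing_mm Isotropic spacing; defaults 0.8 (preclinical) or
#'   2.0 (clinical) mm.
#' @param tumor_radius_range_mm Semi-axis sampling interval; defaults
#'   c(4, 7) preclinical, c(12, 22) clinical.
#' @param texture_correlation_length_mm Smoothing kernel sigma; defaults
#'   1.6 / 4.0 mm.
#' @param background_suv Background uptake level.
#' @param tumor_suv_mean Mean tumor uptake.
#' @param texture_amplitude Heterogeneity amplitude as a fraction of
#'   `tumor_suv_mean`.
#' @param noise_sd Voxel noise SD (SUV units).
#' @param retest_jitter Fractional day-2 perturbation of intensities and
#'   tumor position; 0 gives identical scans.
#' @param responder_fraction Fraction of subjects assigned `response`.
#' @param effect_size Multiplier separating responder from non-responder
#'   baseline heterogeneity (and its on-treatment change); 0 plants no
#'   class signal in the images.
#' @param seed Integer master seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(arm = c("preclinical", "clinical"),
                           n_subjects = 30L,
                           voxel_spacing_mm = NULL,
                           tumor_radius_range_mm = NULL,
                           texture_correlation_length_mm = NULL,
                           background_suv = 0.5,
                           tumor_suv_mean = 3.0,
                           texture_amplitude = 0.4,
                           noise_sd = 0.10,
                           retest_jitter = 0.05,
                           responder_fraction = 0.5,
                           effect_size = 1.0,
                           seed = 1L) {
  arm <- match.arg(arm)
  if (is.null(voxel_spacing_mm)) {
    voxel_spacing_mm <- if (arm == "preclinical") 0.8 else 2.0
  }
  if (is.null(tumor_radius_range_mm)) {
    tumor_radius_range_mm <- if (arm == "preclinical") c(4, 7) else c(12, 22)
  }
  if (is.null(texture_correlation_length_mm)) {
    texture_correlation_length_mm <- if (arm == "preclinical") 1.6 else 4.0
  }
  cfg <- list(arm = arm, n_subjects = as.integer(n_subjects),
              voxel_spacing_mm = rep(voxel_spacing_mm, length.out = 3),
              tumor_radius_range_mm = sort(tumor_radius_range_mm),
              texture_correlation_length_mm = texture_correlation_length_mm,
              background_suv = background_suv,
              tumor_suv_mean = tumor_suv_mean,
              texture_amplitude = texture_amplitude,
              noise_sd = noise_sd, retest_jitter = retest_jitter,
              responder_fraction = responder_fraction,
              effect_size = effect_size, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_subjects >= 1, all(voxel_spacing_mm > 0),
              all(tumor_radius_range_mm > 0),
              texture_correlation_length_mm > 0,
              background_suv > 0, tumor_suv_mean > 0,
              texture_amplitude >= 0, noise_sd >= 0, retest_jitter >= 0,
              responder_fraction >= 0, responder_fraction <= 1,
              effect_size >= 0)
  })
  structure(cfg, class = "phantom_config")
}

# Grid side length (voxels, odd) large enough for the configured tumors.
phantom_grid_dim <- function(config) {
  margin_mm <- max(4 * max(config$voxel_spacing_mm),
                   2 * config$texture_correlation_length_mm)
  fov_mm <- 2 * max(config$tumor_radius_range_mm) + 2 * margin_mm
  n <- ceiling(fov_mm / config$voxel_spacing_mm)  # per-axis dims
  as.integer(n + (n %% 2 == 0))                   # odd
}

# Latent per-subject tumor: semi-axes and a reproducible field seed.
phantom_tumor <- function(config, subject_id) {
  s <- derive_seed(config$seed, "tumor", subject_id)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(s)
  axes <- stats::runif(3, config$tumor_radius_range_mm[1],
                       config$tumor_radius_range_mm[2])
  list(axes_mm = axes, field_seed = derive_seed(s, "field"),
       shift_dir = stats::rnorm(3))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

# Render a tumor into a scan: ellipsoid mask + correlated texture + noise.
render_phantom <- function(config, subject_id, timepoint, axes_mm,
                           center_offset_mm = c(0, 0, 0),
                           amplitude_mult = 1, field_seed, noise_seed,
                           field_blend = NULL) {
  sp <- config$voxel_spacing_mm
  dm <- rep(phantom_grid_dim(config), length.out = 3)
  if (any(2 * axes_mm >= (dm - 2) * sp)) {
    stop("tumor larger than the phantom field of view")
  }
  cx <- lapply(1:3, function(k) (seq_len(dm[k]) - (dm[k] + 1) / 2) * sp[k] -
                 center_offset_mm[k])
  e1 <- (cx[[1]] / axes_mm[1])^2
  e2 <- (cx[[2]] / axes_mm[2])^2
  e3 <- (cx[[3]] / axes_mm[3])^2
  mask <- outer(outer(e1, e2, `+`), e3, `+`) <= 1
  if (!any(mask)) stop("tumor larger than field of view or degenerate")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  field <- function(fs) {
    set.seed(fs)
    w <- array(stats::rnorm(prod(dm)), dm)
    g <- conv3d(w, gaussian_kernel3(config$texture_correlation_length_mm / sp))
    g / max(stats::sd(g), 1e-12)
  }
  G <- field(field_seed)
  if (!is.null(field_blend)) {
    j <- field_blend$weight
    if (j > 0) {
      G2 <- field(field_blend$field_seed)
      G <- ((1 - j) * G + j * G2) / sqrt((1 - j)^2 + j^2)
    }
  }
  amp <- config$texture_amplitude * config$tumor_suv_mean * amplitude_mult
  suv <- array(config$background_suv, dm)
  suv[mask] <- config$tumor_suv_mean + amp * G[mask]
  set.seed(noise_seed)
  if (config$noise_sd > 0) {
    suv <- suv + config$noise_sd * array(stats::rnorm(prod(dm)), dm)
  }
  suv[suv < 0] <- 0

  set.seed(derive_seed(noise_seed, "meta", subject_id))
  if (config$arm == "preclinical") {
    dose <- stats::runif(1, 6.66e6, 8.14e6)     # 6.66-8.14 MBq
    weight <- stats::runif(1, 20, 28)           # g
    sex <- NA_character_; height <- NA_real_
  } else {
    dose <- stats::runif(1, 3.3e8, 4.1e8)       # ~10 mCi
    weight <- stats::runif(1, 55, 90) * 1000
    sex <- "F"; height <- stats::runif(1, 150, 178)
  }
  activity <- suv * dose / weight
  scan_record(subject_id, activity, mask, sp, arm = config$arm,
              timepoint = timepoint, units = "Bq/mL",
              injected_dose_bq = dose, body_weight_g = weight,
              sex = sex, height_cm = height)
}

#' Generate one phantom scan
#'
#' @param config A [phantom_config()].
#' @param subject_id Subject identifier.
#' @param timepoint `"BL"` or `"ONTX"`.
#' @param axes_mm Optional explicit ellipsoid semi-axes (mm, length 1 or 3);
#'   default samples them from the configured range.
#' @return A [scan_record()] (activity units, so SUV normalization is
#'   exercised downstream).
#' @export
generate_scan <- function(config, subject_id, timepoint = "BL",
                          axes_mm = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  tum <- phantom_tumor(config, subject_id)
  if (!is.null(axes_mm)) tum$axes_mm <- rep(axes_mm, length.out = 3)
  render_phantom(config, subject_id, timepoint,
                 axes_mm = tum$axes_mm,
                 field_seed = tum$field_seed,
                 noise_seed = derive_seed(config$seed, "noise", subject_id,
                                          timepoint))
}

#' Generate a test-retest scan pair
#'
#' Day 2 is a perturbed re-realization of day 1: the same underlying tumor,
#' with the texture field blended with a fresh realization (weight
#' `retest_jitter`), the tumor shifted sub-voxel, and voxel noise redrawn.
#' With `retest_jitter = 0` the two scans are bit-identical.
#'
#' @param config A [phantom_config()].
#' @param subject_id Subject identifier.
#' @return List with elements `day1` and `day2` ([scan_record()]s).
#' @export
generate_test_retest_pair <- function(config, subject_id) {
  stopifnot(inherits(config, "phantom_config"))
  tum <- phantom_tumor(config, subject_id)
  j <- config$retest_jitter
  n1 <- derive_seed(config$seed, "noise", subject_id, "D1")
  day1 <- render_phantom(config, subject_id, "BL", tum$axes_mm,
                         field_seed = tum$field_seed, noise_seed = n1)
  if (j == 0) {
    day2 <- day1
  } else {
    shift <- j * config$voxel_spacing_mm *
      tum$shift_dir / sqrt(sum(tum$shift_dir^2))
    day2 <- render_phantom(
      config, subject_id, "BL", tum$axes_mm,
      center_offset_mm = shift,
      field_seed = tum$field_seed,
      noise_seed = derive_seed(config$seed, "noise", subject_id, "D2"),
      field_blend = list(weight = j,
                         field_seed = derive_seed(tum$field_seed, "retest")))
  }
  list(day1 = day1, day2 = day2)
}

#' Generate a longitudinal (BL + on-treatment) phantom cohort
#'
#' Subjects are assigned latent classes (`response` / `partial` /
#' `no_response`): `round(responder_fraction * n)` responders, the remainder
#' split evenly between partial and no response. Responders shrink by more
#' than 20% in volume by the endpoint (partials stay within +/-20%,
#' non-responders grow by more than 20%), and `effect_size` scales the extra
#' baseline heterogeneity (and its on-treatment decline) planted in
#' responders; `effect_size = 0` leaves baseline images exchangeable across
#' classes.
#'
#' @param config A [phantom_config()].
#' @return List: `scans` (BL and ONTX [scan_record()]s), `labels`
#'   (data.frame with `subject_id`, `class`, `volume_change_pct`).
#' @export
generate_longitudinal_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$n_subjects
  n_resp <- round(config$responder_fraction * n)
  n_rest <- n - n_resp
  classes <- c(rep("response", n_resp),
               rep("partial", ceiling(n_rest / 2)),
               rep("no_response", floor(n_rest / 2)))
  old <- .Random.seed_save()
  set.seed(derive_seed(config$seed, "classes"))
  classes <- sample(classes)
  .Random.seed_restore(old)

  scans <- list()
  labels <- data.frame(subject_id = character(n), class = character(n),
                       volume_change_pct = numeric(n))
  for (i in seq_len(n)) {
    sid <- sprintf("S%03d", i)
    cls <- classes[i]
    tum <- phantom_tumor(config, sid)
    old <- .Random.seed_save()
    set.seed(derive_seed(config$seed, "dynamics", sid))
    pct <- switch(cls,
                  response = stats::runif(1, -60, -25),
                  partial = stats::runif(1, -15, 15),
                  no_response = stats::runif(1, 25, 60))
    .Random.seed_restore(old)
    g <- (1 + pct / 100)^(1 / 3)
    amp_bl <- if (cls == "response") 1 + config$effect_size else 1
    amp_tx <- if (cls == "response") 1 + 0.3 * config$effect_size else 1
    bl <- render_phantom(config, sid, "BL", tum$axes_mm,
                         amplitude_mult = amp_bl,
                         field_seed = tum$field_seed,
                         noise_seed = derive_seed(config$seed, "noise", sid, "BL"))
    tx <- render_phantom(config, sid, "ONTX", tum$axes_mm * g,
                         amplitude_mult = amp_tx,
                         field_seed = derive_seed(tum$field_seed, "ontx"),
                         noise_seed = derive_seed(config$seed, "noise", sid, "ONTX"))
    scans[[length(scans) + 1L]] <- bl
    scans[[length(scans) + 1L]] <- tx
    labels$subject_id[i] <- sid
    labels$class[i] <- cls
    labels$volume_change_pct[i] <- pct
  }
  labels$class <- factor(labels$class,
                         levels = c("response", "partial", "no_response"))
  list(scans = scans, labels = labels)
}

#' Simulate a feature-space cohort with planted signal
#'
#' A feature-table-level phantom for selection/classification studies: `n`
#' instances with `n_signal` discriminative features (class means separated
#' by `effect` within-class SDs) among `n_noise` standard-normal decoys.
#'
#' @param n Instances per cohort.
#' @param n_signal Number of planted discriminative features.
#' @param n_noise Number of decoy features.
#' @param effect Class-mean separation in SD units.
#' @param classes Number of classes (default 2, balanced).
#' @param seed Integer seed.
#' @return List: `table` (data.frame), `labels` (factor), `signal_names`.
#' @export
simulate_feature_table <- function(n = 60L, n_signal = 4L, n_noise = 16L,
                                   effect = 2, classes = 2L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  y <- factor(rep(paste0("C", seq_len(classes)), length.out = n))
  y <- y[sample(n)]
  mu <- (as.integer(y) - 1) * effect
  sig <- matrix(stats::rnorm(n * n_signal), n, n_signal) + mu
  noi <- matrix(stats::rnorm(n * n_noise), n, n_noise)
  tab <- as.data.frame(cbind(sig, noi))
  names(tab) <- c(sprintf("signal_%02d", seq_len(n_signal)),
                  sprintf("decoy_%02d", seq_len(n_noise)))
  list(table = tab, labels = y,
       signal_names = names(tab)[seq_len(n_signal)])
}
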