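# Non-radiomic quantitation: SUV normalization, the SUV/SUL summary panel,
# caliper volumes, metabolic tumor volume, and response labeling.

#' Voxelwise SUV normalization
#'
#' Standardized uptake value: activity concentration normalized by injected
#' dose per unit body weight, `SUV = activity (Bq/mL) x weight (g) / dose (Bq)`.
#' The transform is linear and order-preserving.
#'
#' @param activity Numeric array or vector of activity concentration in Bq/mL.
#' @param body_weight_g Body weight in grams (> 0).
#' @param injected_dose_bq Injected dose in Bq (> 0).
#' @return SUV values with the shape of `activity`.
#' @export
normalize_suv <- function(activity, body_weight_g, injected_dose_bq) {
  if (!is.finite(body_weight_g) || body_weight_g <= 0) {
    stop("body_weight_g must be > 0")
  }
  if (!is.finite(injected_dose_bq) || injected_dose_bq <= 0) {
    stop("injected_dose_bq must be > 0")
  }
  activity * body_weight_g / injected_dose_bq
}

#' Lean body mass (Janmahasatian)
#'
#' Sex-specific lean body mass used for SUL normalization of clinical scans:
#' `LBM = 9270 W / (6680 + 216 BMI)` for males and
#' `LBM = 9270 W / (8780 + 244 BMI)` for females, with W in kg and
#' `BMI = W / height_m^2`.
#'
#' @param sex `"F"` or `"M"`.
#' @param body_weight_kg Body weight, kg.
#' @param height_cm Height, cm.
#' @return Lean body mass in kg.
#' @export
lean_body_mass_kg <- function(sex, body_weight_kg, height_cm) {
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0 ||
      !is.finite(height_cm) || height_cm <= 0) {
    stop("weight and height must be positive")
  }
  bmi <- body_weight_kg / (height_cm / 100)^2
  if (identical(sex, "M")) {
    9270 * body_weight_kg / (6680 + 216 * bmi)
  } else if (identical(sex, "F")) {
    9270 * body_weight_kg / (8780 + 244 * bmi)
  } else {
    stop("sex must be 'F' or 'M' for lean body mass")
  }
}

# SUL/SUV conversion factor for a scan: LBM/weight for clinical records with
# sex and height available, 1 for preclinical (LBM is undefined for mice, so
# SUL == SUV in the preclinical arm).
sul_factor <- function(scan) {
  if (scan$arm == "clinical" && !is.na(scan$sex) && is.finite(scan$height_cm)) {
    lbm_kg <- lean_body_mass_kg(scan$sex, scan$body_weight_g / 1000, scan$height_cm)
    lbm_kg * 1000 / scan$body_weight_g
  } else {
    1
  }
}

#' Peak SUV over a ~1 mL sphere
#'
#' PERCIST-style peak uptake: the largest mean SUV over a sphere of fixed
#' volume (default 1 mL) realized on the voxel grid and centered at each
#' in-mask voxel (ties broken by the first voxel in column-major scan order).
#' Voxels outside the field of view contribute zero. If the whole VOI is
#' smaller than the sphere the whole-VOI mean is returned and flagged.
#'
#' @param scan A [scan_record()] (normalized to SUV internally).
#' @param sphere_volume_ml Sphere volume in mL.
#' @return List with `suv_peak`, `sul_peak` (lean-body-mass scaled for
#'   clinical scans), and `peak_fallback` (TRUE when the whole-VOI mean was
#'   used).
#' @export
suv_peak <- function(scan, sphere_volume_ml = 1.0) {
  scan <- suv_image(scan)
  vox_ml <- prod(scan$spacing_mm) / 1000
  voi_ml <- sum(scan$mask) * vox_ml
  if (voi_ml < sphere_volume_ml) {
    pk <- mean(scan$image[scan$mask])
    fallback <- TRUE
  } else {
    r_mm <- (3 * sphere_volume_ml * 1000 / (4 * pi))^(1 / 3)
    kern <- sphere_kernel(r_mm, scan$spacing_mm)
    means <- conv3d(scan$image, kern * 1) / sum(kern)
    pk <- max(means[scan$mask])
    fallback <- FALSE
  }
  list(suv_peak = pk, sul_peak = pk * sul_factor(scan), peak_fallback = fallback)
}

#' Metabolic tumor volume
#'
#' Volume of in-mask voxels with SUV at or above a fraction of the in-mask
#' maximum (default 40%).
#'
#' @param scan A [scan_record()].
#' @param fraction_of_max Threshold fraction in `[0, 1]`.
#' @return MTV in mL.
#' @export
metabolic_tumor_volume <- function(scan, fraction_of_max = 0.40) {
  scan <- suv_image(scan)
  v <- scan$image[scan$mask]
  thr <- fraction_of_max * max(v)
  sum(v >= thr) * prod(scan$spacing_mm) / 1000
}

#' SUV summary panel for one scan
#'
#' The nine SUV/SUL metrics plus the two volumes carried in the 131-feature
#' panel: SUVmean, SUVmax, SUVpeak, SULpeak, SULmean, SUVmin, SUVsd,
#' SUVmedian, TLG (= SUVmean x MTV), tumor volume, and metabolic tumor
#' volume.
#'
#' @inheritParams suv_peak
#' @param mtv_fraction Fraction of SUVmax defining the MTV threshold.
#' @return Named list of metrics (volumes in mL, TLG in SUV·mL).
#' @export
suv_summary <- function(scan, sphere_volume_ml = 1.0, mtv_fraction = 0.40) {
  scan <- suv_image(scan)
  v <- scan$image[scan$mask]
  if (length(v) == 0) stop("empty mask")
  pk <- suv_peak(scan, sphere_volume_ml)
  f <- sul_factor(scan)
  vol_ml <- length(v) * prod(scan$spacing_mm) / 1000
  mtv_ml <- metabolic_tumor_volume(scan, mtv_fraction)
  list(
    suv_mean = mean(v), suv_max = max(v), suv_peak = pk$suv_peak,
    sul_peak = pk$sul_peak, sul_mean = mean(v) * f,
    suv_min = min(v), suv_sd = stats::sd(v), suv_median = stats::median(v),
    tlg = mean(v) * mtv_ml,
    tumor_volume = vol_ml, mtv = mtv_ml,
    peak_fallback = pk$peak_fallback
  )
}

#' Caliper tumor volume
#'
#' Preclinical caliper volume from the long axis L and width W (both mm),
#' `V = 1/6 L W^2` as used in the PDX therapy studies. The common ellipsoid
#' convention `V = pi/6 L W^2` is available via `ellipsoid = TRUE`.
#'
#' @param L Tumor length in mm (long axis), `L >= W`.
#' @param W Tumor width in mm.
#' @param ellipsoid Use the `pi/6` ellipsoid variant.
#' @return Volume in mm^3.
#' @export
caliper_volume <- function(L, W, ellipsoid = FALSE) {
  if (any(!is.finite(L)) || any(!is.finite(W)) || any(L < 0) || any(W < 0)) {
    stop("L and W must be nonnegative")
  }
  k <- if (ellipsoid) pi / 6 else 1 / 6
  k * L * W^2
}

#' Percent change from baseline
#'
#' `100 (followup - baseline) / baseline`; reductions are negative.
#'
#' @param baseline Baseline value (nonzero).
#' @param followup Follow-up value.
#' @return Percent change.
#' @export
percent_change <- function(baseline, followup) {
  if (any(baseline == 0)) stop("baseline must be nonzero")
  100 * (followup - baseline) / baseline
}

#' Trichotomous preclinical response label
#'
#' Endpoint caliper-volume change classifies preclinical response:
#' more than 20% decrease is `response`, change within +/-20% (inclusive) is
#' `partial`, and more than 20% increase is `no_response`.
#'
#' @param volume_change_pct Percent volume change (finite).
#' @return Factor with levels `response`, `partial`, `no_response`.
#' @export
classify_preclinical_response <- function(volume_change_pct) {
  if (any(!is.finite(volume_change_pct))) stop("volume change must be finite")
  lab <- ifelse(volume_change_pct < -20, "response",
                ifelse(volume_change_pct > 20, "no_response", "partial"))
  factor(lab, levels = c("response", "partial", "no_response"))
}
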