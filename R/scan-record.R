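#' Construct a single-acquisition scan record
#'
#' A scan record bundles one PET acquisition: a 3D voxel grid (raw activity in
#' Bq/mL or already-normalized SUV), an aligned binary tumor mask, the voxel
#' spacing, and the subject/timepoint/dose metadata needed for SUV and lean
#' body mass normalization.
#'
#' @param subject_id Subject identifier (character or coercible).
#' @param image 3D numeric array, nonnegative; Bq/mL if `units = "Bq/mL"`,
#'   dimensionless SUV if `units = "SUV"`.
#' @param mask 3D logical (or 0/1) array with the same dimensions as `image`;
#'   must contain at least one foreground voxel.
#' @param spacing_mm Positive length-3 voxel spacing in mm (x, y, z).
#' @param arm `"preclinical"` or `"clinical"`.
#' @param timepoint `"BL"` (baseline) or `"ONTX"` (on-treatment).
#' @param units `"Bq/mL"` or `"SUV"`.
#' @param injected_dose_bq Injected tracer dose in Bq (> 0).
#' @param body_weight_g Body weight in grams (> 0).
#' @param sex `"F"`, `"M"`, or `NA` (needed for clinical lean-body-mass).
#' @param height_cm Height in cm, or `NA` (preclinical).
#'
#' @return An object of class `scan_record`.
#' @export
scan_record <- function(subject_id, image, mask, spacing_mm,
                        arm = c("preclinical", "clinical"),
                        timepoint = c("BL", "ONTX"),
                        units = c("Bq/mL", "SUV"),
                        injected_dose_bq, body_weight_g,
                        sex = NA_character_, height_cm = NA_real_) {
  arm <- match.arg(arm)
  timepoint <- match.arg(timepoint)
  units <- match.arg(units)
  image <- as_array3d(image)
  mask <- as_array3d(mask) > 0
  if (!identical(dim(image), dim(mask))) {
    stop("image and mask must have identical dimensions")
  }
  if (!any(mask)) stop("mask has no foreground voxels")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("spacing_mm must be three positive values")
  }
  if (!is.finite(injected_dose_bq) || injected_dose_bq <= 0) {
    stop("injected_dose_bq must be > 0")
  }
  if (!is.finite(body_weight_g) || body_weight_g <= 0) {
    stop("body_weight_g must be > 0")
  }
  structure(
    list(subject_id = as.character(subject_id), arm = arm,
         timepoint = timepoint, image = image, mask = mask,
         spacing_mm = as.numeric(spacing_mm), units = units,
         injected_dose_bq = injected_dose_bq, body_weight_g = body_weight_g,
         sex = sex, height_cm = height_cm),
    class = "scan_record"
  )
}

as_array3d <- function(x) {
  if (is.null(dim(x))) stop("expected a 3D array")
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3) stop("expected a 3D array")
  x
}

#' @export
print.scan_record <- function(x, ...) {
  cat(sprintf("<scan_record> %s [%s, %s] %s grid %s, spacing %s mm, %d mask voxels\n",
              x$subject_id, x$arm, x$timepoint, x$units,
              paste(dim(x$image), collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

#' SUV image of a scan record
#'
#' Returns the scan with its image voxelwise-normalized to SUV. Records
#' already in SUV units are returned unchanged; activity images are converted
#' with [normalize_suv()] using the record's dose and weight.
#'
#' @param scan A [scan_record()].
#' @return A `scan_record` with `units == "SUV"`.
#' @export
suv_image <- function(scan) {
  stopifnot(inherits(scan, "scan_record"))
  if (scan$units == "SUV") return(scan)
  scan$image <- normalize_suv(scan$image, scan$body_weight_g, scan$injected_dose_bq)
  scan$units <- "SUV"
  scan
}
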