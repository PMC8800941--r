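# NIfTI round-trip for phantom cohorts: image+mask pairs plus a CSV manifest
# (subject_id, arm, timepoint, dose, weight, label).

#' Write a cohort of scans as NIfTI image/mask pairs
#'
#' @param scans List of [scan_record()]s.
#' @param dir Output directory (created if absent).
#' @param labels Optional data.frame with `subject_id` and `class` merged
#'   into the manifest.
#' @return Invisibly, the manifest data.frame (also written to
#'   `manifest.csv`).
#' @export
write_cohort_nifti <- function(scans, dir, labels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(scans, function(s) {
    stem <- sprintf("%s_%s", s$subject_id, s$timepoint)
    img_path <- file.path(dir, paste0(stem, "_image.nii.gz"))
    msk_path <- file.path(dir, paste0(stem, "_mask.nii.gz"))
    img <- RNifti::asNifti(s$image)
    RNifti::pixdim(img) <- s$spacing_mm
    msk <- RNifti::asNifti(s$mask * 1L)
    RNifti::pixdim(msk) <- s$spacing_mm
    RNifti::writeNifti(img, img_path)
    RNifti::writeNifti(msk, msk_path)
    data.frame(subject_id = s$subject_id, arm = s$arm,
               timepoint = s$timepoint, units = s$units,
               injected_dose_bq = s$injected_dose_bq,
               body_weight_g = s$body_weight_g,
               sex = ifelse(is.na(s$sex), "", s$sex),
               height_cm = s$height_cm,
               image = basename(img_path), mask = basename(msk_path),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  if (!is.null(labels)) {
    manifest <- merge(manifest, labels, by = "subject_id", all.x = TRUE,
                      sort = FALSE)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort_nifti()]
#'
#' @param dir Directory containing `manifest.csv` and the NIfTI pairs.
#' @return List of [scan_record()]s.
#' @export
read_cohort_nifti <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    img <- RNifti::readNifti(file.path(dir, m$image))
    msk <- RNifti::readNifti(file.path(dir, m$mask))
    spacing <- RNifti::pixdim(img)[1:3]
    img <- array(as.numeric(img), dim(img))
    msk <- array(as.numeric(msk), dim(msk))
    scan_record(m$subject_id, img, msk > 0, spacing,
                arm = m$arm, timepoint = m$timepoint, units = m$units,
                injected_dose_bq = m$injected_dose_bq,
                body_weight_g = m$body_weight_g,
                sex = if (nzchar(m$sex %||% "")) m$sex else NA_character_,
                height_cm = m$height_cm)
  })
}
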