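# Panel assembly: the versioned 131-feature manifest and the per-scan
# extraction pipeline (raw branch for first-order and SUV metrics; resampled
# + quantized branch for all texture families).

#' The 131-feature panel manifest
#'
#' Ordered descriptor of the full panel: 37 first-order features, 83 texture
#' features (GLCM 25, GLRLM 16, GLSZM 16, GLDZM 16, NGTDM 5, GLDM 5), tumor
#' volume, metabolic tumor volume, and 9 SUV metrics — 131 in total, 120 of
#' them radiomic (first-order + texture).
#'
#' @return data.frame with columns `name`, `family`, `preprocessing`, plus
#'   attribute `version`.
#' @export
feature_manifest <- function() {
  if (!is.null(.petrad_cache$manifest)) return(.petrad_cache$manifest)
  fo <- first_order_features(.manifest_probe_scan())
  tex <- list(glcm = 25L, glrlm = 16L, glszm = 16L, gldzm = 16L,
              ngtdm = 5L, gldm = 5L)
  qp <- equalize_quantize(.manifest_probe_scan()$image,
                          .manifest_probe_scan()$mask, 8L)
  tex_names <- c(names(glcm_features(qp)), names(glrlm_features(qp)),
                 names(glszm_features(qp)), names(gldzm_features(qp)),
                 names(ngtdm_features(qp)), names(gldm_features(qp)))
  suv_names <- c("suv_mean", "suv_max", "suv_peak", "sul_peak", "sul_mean",
                 "suv_min", "suv_sd", "suv_median", "tlg")
  m <- rbind(
    data.frame(name = names(fo), family = "first_order", preprocessing = "raw"),
    data.frame(name = tex_names,
               family = sub("\\..*$", "", tex_names),
               preprocessing = "quantized+resampled"),
    data.frame(name = "tumor_volume", family = "volume", preprocessing = "raw"),
    data.frame(name = "mtv", family = "mtv", preprocessing = "raw"),
    data.frame(name = suv_names, family = "suv_metric", preprocessing = "raw")
  )
  rownames(m) <- NULL
  stopifnot(nrow(m) == 131L, !anyDuplicated(m$name),
            sum(m$family == "first_order") == 37L)
  attr(m, "version") <- "petrad-131-v1"
  .petrad_cache$manifest <- m
  m
}

.petrad_cache <- new.env(parent = emptyenv())

# Small deterministic probe scan used only to enumerate feature names.
.manifest_probe_scan <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(1)
    img <- array(stats::runif(5^3, 1, 2), c(5, 5, 5))
    msk <- array(TRUE, c(5, 5, 5))
    cache <<- scan_record("probe", img, msk, 1, arm = "preclinical",
                          units = "SUV", injected_dose_bq = 1, body_weight_g = 1)
    cache
  }
})

#' Extract the full 131-feature vector from one scan
#'
#' First-order features and SUV metrics are computed on the raw SUV grid;
#' texture families are computed after isotropic resampling (trilinear image
#' / nearest-neighbour mask) and `ng`-level equal-probability quantization,
#' with texture matrices restricted to the mask bounding box. The identical
#' pipeline is applied to preclinical and clinical scans.
#'
#' A family that fails on a degenerate input yields `NA` for its features; if
#' more than 10% of the panel is `NA` the extraction errors.
#'
#' @param scan A [scan_record()].
#' @param ng Gray levels for the texture branch (default 64).
#' @param target_spacing_mm Isotropic target spacing; default is the smallest
#'   native spacing of the scan.
#' @param sphere_volume_ml Peak-sphere volume for SUVpeak/SULpeak.
#' @param mtv_fraction MTV threshold as a fraction of SUVmax.
#' @return Named numeric vector of length 131 ordered as [feature_manifest()].
#' @export
extract_features <- function(scan, ng = 64L, target_spacing_mm = NULL,
                             sphere_volume_ml = 1.0, mtv_fraction = 0.40) {
  scan <- suv_image(scan)
  if (is.null(target_spacing_mm)) target_spacing_mm <- min(scan$spacing_mm)
  try_block <- function(expr, n, prefix) {
    out <- tryCatch(expr, error = function(e) {
      stats::setNames(rep(NA_real_, n), paste0(prefix, ".failed", seq_len(n)))
    })
    out
  }

  fo <- try_block(first_order_features(scan, ng), 37L, "fo")

  tex <- tryCatch({
    rs <- resample_isotropic(scan$image, scan$mask, scan$spacing_mm,
                             target_spacing_mm)
    cr <- crop_to_mask(rs$image, rs$mask)
    q <- equalize_quantize(cr$image, cr$mask, ng)
    c(try_block(glcm_features(q), 25L, "glcm"),
      try_block(glrlm_features(q), 16L, "glrlm"),
      try_block(glszm_features(q), 16L, "glszm"),
      try_block(gldzm_features(q), 16L, "gldzm"),
      try_block(ngtdm_features(q), 5L, "ngtdm"),
      try_block(gldm_features(q), 5L, "gldm"))
  }, error = function(e) rep(NA_real_, 83L))

  sv <- try_block({
    s <- suv_summary(scan, sphere_volume_ml, mtv_fraction)
    unlist(s[c("tumor_volume", "mtv", "suv_mean", "suv_max", "suv_peak",
               "sul_peak", "sul_mean", "suv_min", "suv_sd", "suv_median",
               "tlg")])
  }, 11L, "suv")

  vec <- c(fo, tex, sv)
  manifest <- feature_manifest()
  if (length(vec) != 131L) stop("internal error: panel length != 131")
  names(vec) <- manifest$name  # families are emitted in manifest order
  n_na <- sum(!is.finite(vec))
  if (n_na > 0.10 * length(vec)) {
    stop(sprintf("feature extraction failed for %d/131 features", n_na))
  }
  vec
}

#' Extract a feature table from a list of scans
#'
#' @param scans List of [scan_record()] objects.
#' @param ... Passed to [extract_features()].
#' @return data.frame: one row per scan with `subject_id`, `arm`,
#'   `timepoint` metadata columns followed by the 131 features.
#' @export
extract_feature_table <- function(scans, ...) {
  rows <- lapply(scans, function(s) {
    v <- extract_features(s, ...)
    cbind(data.frame(subject_id = s$subject_id, arm = s$arm,
                     timepoint = s$timepoint, stringsAsFactors = FALSE),
          as.data.frame(as.list(v), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature columns of a feature table
#'
#' @param table A feature table from [extract_feature_table()].
#' @return Character vector of the 131 feature column names present.
#' @export
feature_columns <- function(table) {
  setdiff(colnames(table), c("subject_id", "arm", "timepoint", "label"))
}

#' Delta (on-treatment minus baseline) feature table
#'
#' Pairs BL and ONTX rows by subject and returns per-subject feature
#' differences, the input for response-assessment models.
#'
#' @param table Feature table containing both timepoints.
#' @return data.frame of per-subject feature differences.
#' @export
delta_feature_table <- function(table) {
  fc <- feature_columns(table)
  bl <- table[table$timepoint == "BL", ]
  tx <- table[table$timepoint == "ONTX", ]
  common <- intersect(bl$subject_id, tx$subject_id)
  if (length(common) == 0) stop("no paired subjects")
  bl <- bl[match(common, bl$subject_id), ]
  tx <- tx[match(common, tx$subject_id), ]
  d <- as.data.frame(as.matrix(tx[, fc]) - as.matrix(bl[, fc]),
                     check.names = FALSE)
  cbind(data.frame(subject_id = common, arm = bl$arm,
                   timepoint = "DELTA", stringsAsFactors = FALSE), d)
}
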