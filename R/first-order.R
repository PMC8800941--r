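# First-order feature block: 18 intensity statistics on the raw in-mask SUV
# values plus 19 intensity-histogram statistics on the Ng-level equalized
# histogram (37 total). Moments are population (1/n) moments; kurtosis is
# excess kurtosis. Degenerate (constant) inputs give 0 for the standardized
# moments and CoV.

fo_stat_block <- function(v) {
  n <- length(v)
  m <- mean(v)
  va <- mean((v - m)^2)
  s <- sqrt(va)
  sk <- if (s > 0) mean((v - m)^3) / s^3 else 0
  ku <- if (s > 0) mean((v - m)^4) / s^4 - 3 else 0
  q <- stats::quantile(v, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  med <- stats::median(v)
  rmad_v <- v[v >= q[1] & v <= q[4]]
  list(
    mean = m, variance = va, skewness = sk, kurtosis = ku, median = med,
    min = min(v), p10 = q[1], p90 = q[4], max = max(v),
    iqr = q[3] - q[2], range = max(v) - min(v),
    mad = mean(abs(v - m)),
    rmad = mean(abs(rmad_v - mean(rmad_v))),
    medad = mean(abs(v - med)),
    cov = if (m != 0) s / m else 0,
    qcod = if ((q[3] + q[2]) != 0) (q[3] - q[2]) / (q[3] + q[2]) else 0
  )
}

#' First-order intensity and intensity-histogram features
#'
#' Computes the 37 first-order features of the panel over in-mask voxels
#' only, with no resampling: 18 statistics of the raw SUV distribution
#' (mean, variance, skewness, excess kurtosis, median, min, p10, p90, max,
#' IQR, range, mean absolute deviation, robust MAD over the p10-p90 core,
#' median absolute deviation, coefficient of variation, quartile coefficient
#' of dispersion, energy, RMS) and 19 statistics of the `ng`-level
#' equal-probability histogram (the same location/dispersion set on bin
#' indices, plus mode, entropy in bits, and uniformity).
#'
#' @param scan A [scan_record()].
#' @param ng Histogram gray levels (default 64).
#' @return Named numeric vector of length 37 (`fo.*`, `ih.*`).
#' @export
first_order_features <- function(scan, ng = 64L) {
  scan <- suv_image(scan)
  v <- scan$image[scan$mask]
  if (length(v) == 0) stop("empty mask")
  fo <- fo_stat_block(v)
  fo$energy <- sum(v^2)
  fo$rms <- sqrt(mean(v^2))

  q <- equalize_quantize(scan$image, scan$mask, ng)
  h <- as.numeric(q$levels[scan$mask])
  ih <- fo_stat_block(h)
  tab <- tabulate(as.integer(h), nbins = ng)
  p <- tab / sum(tab)
  pp <- p[p > 0]
  ih$mode <- which.max(tab)  # smallest level on ties
  ih$entropy <- -sum(pp * log2(pp))
  ih$uniformity <- sum(p^2)

  fo_order <- c("mean", "variance", "skewness", "kurtosis", "median", "min",
                "p10", "p90", "max", "iqr", "range", "mad", "rmad", "medad",
                "cov", "qcod", "energy", "rms")
  ih_order <- c("mean", "variance", "skewness", "kurtosis", "median", "min",
                "p10", "p90", "max", "mode", "iqr", "range", "mad", "rmad",
                "medad", "cov", "qcod", "entropy", "uniformity")
  out <- c(stats::setNames(unlist(fo[fo_order]), paste0("fo.", fo_order)),
           stats::setNames(unlist(ih[ih_order]), paste0("ih.", ih_order)))
  out
}
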