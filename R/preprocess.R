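# Preprocessing for the higher-order feature branch: isotropic resampling and
# equal-probability gray-level quantization. First-order features bypass both
# and are computed on the raw SUV grid.

#' Resample an image and mask to isotropic voxels
#'
#' Trilinear interpolation for the image, nearest neighbour for the mask,
#' with the resampled grid center-aligned to the source grid. When the input
#' is already isotropic at the target spacing the arrays are returned
#' untouched.
#'
#' @param image 3D numeric array.
#' @param mask 3D logical array, same dims.
#' @param spacing_mm Source voxel spacing (length 3, mm).
#' @param target_mm Target isotropic spacing (scalar, mm).
#' @return List `image`, `mask`, `spacing_mm`.
#' @export
resample_isotropic <- function(image, mask, spacing_mm, target_mm) {
  spacing_mm <- rep(spacing_mm, length.out = 3)
  if (any(spacing_mm <= 0) || target_mm <= 0) stop("spacings must be positive")
  if (max(abs(spacing_mm - target_mm)) < 1e-9) {
    return(list(image = image, mask = mask, spacing_mm = rep(target_mm, 3)))
  }
  d <- dim(image)
  nd <- pmax(1L, as.integer(round(d * spacing_mm / target_mm)))
  # continuous source index of each new voxel center (grids center-aligned)
  src_u <- function(k) {
    ((seq_len(nd[k]) - (nd[k] + 1) / 2) * target_mm) / spacing_mm[k] + (d[k] + 1) / 2
  }
  u <- lapply(1:3, src_u)
  cl <- function(x, n) pmin(pmax(x, 1), n)
  lo <- lapply(1:3, function(k) pmin(pmax(floor(u[[k]]), 1L), max(d[k] - 1L, 1L)))
  fr <- lapply(1:3, function(k) cl(u[[k]], d[k]) - lo[[k]])
  hi <- lapply(1:3, function(k) pmin(lo[[k]] + 1L, d[k]))

  n_new <- prod(nd)
  gx <- rep(seq_len(nd[1]), times = nd[2] * nd[3])
  gy <- rep(rep(seq_len(nd[2]), each = nd[1]), times = nd[3])
  gz <- rep(seq_len(nd[3]), each = nd[1] * nd[2])
  out <- numeric(n_new)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx == 0) lo[[1]][gx] else hi[[1]][gx]
    iy <- if (cy == 0) lo[[2]][gy] else hi[[2]][gy]
    iz <- if (cz == 0) lo[[3]][gz] else hi[[3]][gz]
    wx <- if (cx == 0) 1 - fr[[1]][gx] else fr[[1]][gx]
    wy <- if (cy == 0) 1 - fr[[2]][gy] else fr[[2]][gy]
    wz <- if (cz == 0) 1 - fr[[3]][gz] else fr[[3]][gz]
    out <- out + image[cbind(ix, iy, iz)] * wx * wy * wz
  }
  new_image <- array(out, nd)
  nn <- lapply(1:3, function(k) as.integer(cl(round(u[[k]]), d[k])))
  new_mask <- array(mask[cbind(nn[[1]][gx], nn[[2]][gy], nn[[3]][gz])], nd)
  if (!any(new_mask)) stop("resampled mask is empty")
  list(image = new_image, mask = new_mask, spacing_mm = rep(target_mm, 3))
}

#' Equal-probability gray-level quantization
#'
#' Histogram-equalization quantization of the in-mask intensities: values are
#' mapped through their empirical CDF into `ng` levels so that level
#' occupancies are as uniform as ties permit. The mapping is monotone
#' nondecreasing, so any strictly monotone intensity transform yields the
#' identical quantized grid.
#'
#' @param image 3D numeric array.
#' @param mask 3D logical array; at least one in-mask voxel.
#' @param ng Number of gray levels (default 64).
#' @return Object of class `quantized_image`: list with `levels` (integer
#'   array, `NA` outside the mask), `ng`, `mask`.
#' @export
equalize_quantize <- function(image, mask, ng = 64L) {
  mask <- mask > 0
  if (!any(mask)) stop("mask has no foreground voxels")
  v <- image[mask]
  cdf <- stats::ecdf(v)(v)
  lev <- pmax(1L, as.integer(ceiling(cdf * ng)))
  levels_arr <- array(NA_integer_, dim(image))
  levels_arr[mask] <- lev
  structure(list(levels = levels_arr, ng = as.integer(ng), mask = mask),
            class = "quantized_image")
}
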