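# Zone-based texture families (direction-free): gray level size zone
# (GLSZM) and gray level distance zone (GLDZM) features. Zones are
# 26-connected components of equal gray level inside the mask; the distance
# of a zone is the minimum city-block distance of its voxels to the mask
# border (border voxels have distance 1).

# Shared small/large + gray-level emphasis feature block used by both zone
# matrices; `s` is the per-zone size (GLSZM) or distance (GLDZM) attribute.
zone_feature_block <- function(lev, s, n_vox) {
  nz <- length(lev)
  tab <- stats::aggregate(rep(1L, nz), by = list(i = lev, j = s), FUN = sum)
  i <- tab$i
  jj <- tab$j
  cnt <- tab$x
  p <- cnt / nz
  mu_i <- sum(i * p)
  mu_j <- sum(jj * p)
  r_i <- tapply(cnt, i, sum)
  r_j <- tapply(cnt, jj, sum)
  c(
    small = sum(cnt / jj^2) / nz,
    large = sum(cnt * jj^2) / nz,
    lgl = sum(cnt / i^2) / nz,
    hgl = sum(cnt * i^2) / nz,
    small_lgl = sum(cnt / (i^2 * jj^2)) / nz,
    small_hgl = sum(cnt * i^2 / jj^2) / nz,
    large_lgl = sum(cnt * jj^2 / i^2) / nz,
    large_hgl = sum(cnt * i^2 * jj^2) / nz,
    gln = sum(r_i^2) / nz,
    glnn = sum(r_i^2) / nz^2,
    zn = sum(r_j^2) / nz,
    znn = sum(r_j^2) / nz^2,
    zp = nz / n_vox,
    glv = sum((i - mu_i)^2 * p),
    zv = sum((jj - mu_j)^2 * p),
    ze = -sum(p * log2(p))
  )
}

#' GLSZM texture features
#'
#' The 16 size-zone features over 26-connected equal-level zones.
#'
#' @param q A `quantized_image` from [equalize_quantize()].
#' @return Named numeric vector (`glszm.*`), length 16.
#' @export
glszm_features <- function(q) {
  z <- label_zones(q$levels, q$mask)
  f <- zone_feature_block(z$zone_level, z$zone_size, sum(q$mask))
  names(f) <- paste0("glszm.", c("sze", "lze", "lglze", "hglze", "szlgle",
                                 "szhgle", "lzlgle", "lzhgle", "gln", "glnn",
                                 "zsn", "zsnn", "zp", "glv", "zv", "ze"))
  f
}

#' GLDZM texture features
#'
#' The 16 distance-zone features: same zones as [glszm_features()], with
#' each zone attributed its minimum city-block distance to the mask border.
#'
#' @param q A `quantized_image` from [equalize_quantize()].
#' @return Named numeric vector (`gldzm.*`), length 16.
#' @export
gldzm_features <- function(q) {
  z <- label_zones(q$levels, q$mask)
  dmap <- distance_map_cityblock(q$mask)
  zone_dist <- as.integer(tapply(dmap[z$voxel_ids], z$membership, min))
  f <- zone_feature_block(z$zone_level, zone_dist, sum(q$mask))
  names(f) <- paste0("gldzm.", c("sde", "lde", "lglze", "hglze", "sdlgle",
                                 "sdhgle", "ldlgle", "ldhgle", "gln", "glnn",
                                 "zdn", "zdnn", "zp", "glv", "zv", "ze"))
  f
}
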