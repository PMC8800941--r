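# Neighbourhood gray tone difference (NGTDM, 5 features) and gray level
# dependence (GLDM, 5 features) families. Both use the 26-neighbourhood on
# the quantized grid, restricted to in-mask voxels.

#' NGTDM texture features
#'
#' Coarseness, contrast, busyness, complexity, and strength from the
#' neighbourhood gray tone difference matrix: for each in-mask voxel with at
#' least one in-mask 26-neighbour, the absolute difference between its level
#' and the mean level of those neighbours is accumulated per gray level.
#'
#' @param q A `quantized_image` from [equalize_quantize()].
#' @return Named numeric vector (`ngtdm.*`), length 5.
#' @export
ngtdm_features <- function(q) {
  lev <- q$levels
  ng <- q$ng
  offs <- offsets_26()
  nb_sum <- array(0, dim(lev))
  nb_cnt <- array(0, dim(lev))
  for (r in seq_len(nrow(offs))) {
    nb <- shift3(lev, offs[r, ])
    has <- !is.na(nb)
    nb_sum <- nb_sum + ifelse(has, nb, 0)
    nb_cnt <- nb_cnt + has
  }
  valid <- q$mask & nb_cnt > 0
  if (!any(valid)) stop("no voxels with in-mask neighbours")
  A <- nb_sum[valid] / nb_cnt[valid]
  L <- lev[valid]
  nv <- length(L)
  n_i <- tabulate(L, nbins = ng)
  s_i <- vapply(seq_len(ng), function(i) sum(abs(i - A)[L == i]), numeric(1))
  p_i <- n_i / nv
  pres <- which(n_i > 0)
  np <- length(pres)

  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6

  if (np > 1) {
    pij <- outer(p_i[pres], p_i[pres])
    dij2 <- outer(pres, pres, function(a, b) (a - b)^2)
    contrast <- sum(pij * dij2) / (np * (np - 1)) * sum(s_i) / nv
    den_b <- sum(abs(outer(pres * p_i[pres], pres * p_i[pres], `-`)))
    busyness <- if (den_b > 0) sum(p_i * s_i) / den_b else 0
    num_c <- outer(pres, pres, function(a, b) abs(a - b)) *
      (outer(p_i[pres] * s_i[pres], p_i[pres] * s_i[pres], `+`)) /
      outer(p_i[pres], p_i[pres], `+`)
    complexity <- sum(num_c) / nv
    num_s <- sum(outer(p_i[pres], p_i[pres], `+`) * dij2)
    strength <- if (sum(s_i) > 0) num_s / sum(s_i) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  out <- c(coarseness = coarseness, contrast = contrast, busyness = busyness,
           complexity = complexity, strength = strength)
  names(out) <- paste0("ngtdm.", names(out))
  out
}

#' GLDM texture features
#'
#' Five dependence-matrix features. The dependence of a voxel is the number
#' of its in-mask 26-neighbours sharing its gray level (alpha = 0); the
#' matrix counts (level, dependence) pairs.
#'
#' @param q A `quantized_image` from [equalize_quantize()].
#' @return Named numeric vector (`gldm.*`), length 5.
#' @export
gldm_features <- function(q) {
  lev <- q$levels
  offs <- offsets_26()
  dep <- array(0L, dim(lev))
  for (r in seq_len(nrow(offs))) {
    nb <- shift3(lev, offs[r, ])
    dep <- dep + (!is.na(nb) & !is.na(lev) & nb == lev)
  }
  d <- dep[q$mask] + 1L  # dependence counts shifted to 1..k
  L <- lev[q$mask]
  nv <- length(L)
  tab <- stats::aggregate(rep(1L, nv), by = list(j = d), FUN = sum)
  p_full <- stats::aggregate(rep(1L, nv), by = list(i = L, j = d), FUN = sum)
  i <- p_full$i
  jj <- p_full$j
  cnt <- p_full$x
  p <- cnt / nv
  mu_j <- sum(jj * p)
  r_j <- tapply(cnt, jj, sum)
  out <- c(
    sde = sum(cnt / jj^2) / nv,
    lde = sum(cnt * jj^2) / nv,
    dnn = sum(r_j^2) / nv^2,
    dv = sum((jj - mu_j)^2 * p),
    de = -sum(p * log2(p))
  )
  names(out) <- paste0("gldm.", names(out))
  out
}
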