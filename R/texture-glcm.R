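# Gray level co-occurrence features. Matrices are built at distance 1 over
# the 13 unique 3D directions, symmetrized and normalized per direction;
# the 25 features are computed per direction and averaged (the "averaged"
# aggregation scheme).

# Symmetric normalized co-occurrence matrix for one direction offset.
glcm_matrix <- function(q, offset) {
  lev <- q$levels
  ng <- q$ng
  nb <- shift3(lev, offset)
  ok <- !is.na(lev) & !is.na(nb)
  if (!any(ok)) return(NULL)
  a <- lev[ok]
  b <- nb[ok]
  counts <- tabulate((a - 1L) * ng + b, nbins = ng * ng)
  M <- matrix(counts, ng, ng, byrow = TRUE)
  M <- M + t(M)
  M / sum(M)
}

glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)  # marginal (symmetric: px == py)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  sig <- sqrt(sig2)

  dvals <- 0:(ng - 1)
  p_dm <- vapply(dvals, function(k) sum(P[abs(i - j) == k]), numeric(1))
  svals <- 2:(2 * ng)
  p_s <- vapply(svals, function(k) sum(P[(i + j) == k]), numeric(1))

  da <- sum(dvals * p_dm)
  sa <- sum(svals * p_s)
  ent0 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

  hxy <- ent0(P)
  pxy <- outer(px, px)
  hxy1 <- -sum(P[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- ent0(pxy)
  hx <- ent0(px)

  offdiag <- i != j
  inv_var <- sum(P[offdiag] / (i[offdiag] - j[offdiag])^2)

  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 1

  c(
    joint_maximum = max(P),
    joint_average = mu,
    joint_variance = sig2,
    joint_entropy = hxy,
    difference_average = da,
    difference_variance = sum((dvals - da)^2 * p_dm),
    difference_entropy = ent0(p_dm),
    sum_average = sa,
    sum_variance = sum((svals - sa)^2 * p_s),
    sum_entropy = ent0(p_s),
    asm = sum(P^2),
    contrast = sum((i - j)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    inverse_difference = sum(P / (1 + abs(i - j))),
    inverse_difference_norm = sum(P / (1 + abs(i - j) / ng)),
    inverse_difference_moment = sum(P / (1 + (i - j)^2)),
    inverse_difference_moment_norm = sum(P / (1 + (i - j)^2 / ng^2)),
    inverse_variance = inv_var,
    correlation = corr,
    autocorrelation = sum(i * j * P),
    cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    info_corr_1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    info_corr_2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  )
}

#' GLCM texture features
#'
#' The 25 co-occurrence features of the panel, averaged over the 13 unique
#' 3D directions at distance 1.
#'
#' @param q A `quantized_image` from [equalize_quantize()].
#' @return Named numeric vector (`glcm.*`), length 25.
#' @export
glcm_features <- function(q) {
  feats <- NULL
  nd <- 0L
  for (r in seq_len(nrow(DIRECTIONS_3D))) {
    P <- glcm_matrix(q, DIRECTIONS_3D[r, ])
    if (is.null(P)) next
    f <- glcm_features_one(P)
    feats <- if (is.null(feats)) f else feats + f
    nd <- nd + 1L
  }
  if (nd == 0L) stop("no voxel pairs in any direction (mask too small)")
  out <- feats / nd
  names(out) <- paste0("glcm.", names(out))
  out
}
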