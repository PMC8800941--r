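# Gray level run length features: runs of identical gray level along each of
# the 13 unique 3D directions; out-of-mask voxels break runs. The 16 features
# are computed per direction and averaged.

# Run-length matrix (ng x max_run) for one direction.
glrlm_matrix <- function(q, offset) {
  lev <- q$levels
  dm <- dim(lev)
  n <- prod(dm)
  ix <- rep(seq_len(dm[1]), times = dm[2] * dm[3])
  iy <- rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3])
  iz <- rep(seq_len(dm[3]), each = dm[1] * dm[2])
  # steps backward to the line start along -offset
  back <- function(p, d, np) {
    if (d == 1) p - 1L else if (d == -1) np - p else rep(n, length(p))
  }
  m <- pmin(back(ix, offset[1], dm[1]),
            pmin(back(iy, offset[2], dm[2]), back(iz, offset[3], dm[3])))
  sx <- ix - m * offset[1]
  sy <- iy - m * offset[2]
  sz <- iz - m * offset[3]
  line_id <- (sx - 1L) + dm[1] * (sy - 1L) + dm[1] * dm[2] * (sz - 1L)
  ord <- order(line_id, m)
  lv <- as.vector(lev)[ord]
  lid <- line_id[ord]
  lv0 <- ifelse(is.na(lv), 0L, lv)  # 0 = out of mask, breaks runs
  brk <- c(TRUE, lid[-1] != lid[-length(lid)] | lv0[-1] != lv0[-length(lv0)])
  run_id <- cumsum(brk)
  run_len <- tabulate(run_id)
  run_lev <- lv0[brk]
  keep <- run_lev > 0
  run_len <- run_len[keep]
  run_lev <- run_lev[keep]
  if (length(run_len) == 0) return(NULL)
  maxr <- max(run_len)
  R <- matrix(0, q$ng, maxr)
  counts <- tabulate((run_lev - 1L) * maxr + run_len, nbins = q$ng * maxr)
  matrix(counts, q$ng, maxr, byrow = TRUE)
}

rlm_features_one <- function(R, n_vox) {
  ns <- sum(R)
  i <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  jj <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
  p <- R / ns
  r_i <- rowSums(R)
  r_j <- colSums(R)
  mu_i <- sum(i * p)
  mu_j <- sum(jj * p)
  pe <- p[p > 0]
  c(
    sre = sum(R / jj^2) / ns,
    lre = sum(R * jj^2) / ns,
    lglre = sum(R / i^2) / ns,
    hglre = sum(R * i^2) / ns,
    srlgle = sum(R / (i^2 * jj^2)) / ns,
    srhgle = sum(R * i^2 / jj^2) / ns,
    lrlgle = sum(R * jj^2 / i^2) / ns,
    lrhgle = sum(R * i^2 * jj^2) / ns,
    gln = sum(r_i^2) / ns,
    glnn = sum(r_i^2) / ns^2,
    rln = sum(r_j^2) / ns,
    rlnn = sum(r_j^2) / ns^2,
    rp = ns / n_vox,
    glv = sum((i - mu_i)^2 * p),
    rlv = sum((jj - mu_j)^2 * p),
    re = -sum(pe * log2(pe))
  )
}

#' GLRLM texture features
#'
#' The 16 run-length features, averaged over the 13 unique 3D directions.
#'
#' @param q A `quantized_image` from [equalize_quantize()].
#' @return Named numeric vector (`glrlm.*`), length 16.
#' @export
glrlm_features <- function(q) {
  n_vox <- sum(q$mask)
  feats <- NULL
  nd <- 0L
  for (r in seq_len(nrow(DIRECTIONS_3D))) {
    R <- glrlm_matrix(q, DIRECTIONS_3D[r, ])
    if (is.null(R)) next
    f <- rlm_features_one(R, n_vox)
    feats <- if (is.null(feats)) f else feats + f
    nd <- nd + 1L
  }
  if (nd == 0L) stop("no runs found")
  out <- feats / nd
  names(out) <- paste0("glrlm.", names(out))
  out
}
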