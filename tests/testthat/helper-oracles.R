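# Independent brute-force oracles for the texture features and ReliefF:
# explicit loops over voxel pairs / runs / zones / neighbours on tiny grids.
# Deliberately shares no code with the package implementation.

bf_dirs <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
)

bf_inside <- function(p, dm) all(p >= 1) && all(p <= dm)

# quantized-image wrapper for handing toy level grids to the package
toy_quantized <- function(lev, ng) {
  structure(list(levels = lev, ng = as.integer(ng), mask = !is.na(lev)),
            class = "quantized_image")
}

## ---- GLCM ----

bf_glcm_matrix <- function(lev, d, ng) {
  dm <- dim(lev)
  M <- matrix(0, ng, ng)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    for (s in c(1L, -1L)) {
      q <- c(x, y, z) + s * d
      if (!bf_inside(q, dm)) next
      b <- lev[q[1], q[2], q[3]]
      if (is.na(b)) next
      M[a, b] <- M[a, b] + 1
    }
  }
  if (sum(M) == 0) return(NULL)
  M / sum(M)
}

bf_glcm_features_one <- function(P) {
  ng <- nrow(P)
  px <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) px[i] <- px[i] + P[i, j]
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) mu <- mu + i * P[i, j]
  f <- c(joint_maximum = max(P), joint_average = mu, joint_variance = 0,
         joint_entropy = 0, difference_average = 0, difference_variance = 0,
         difference_entropy = 0, sum_average = 0, sum_variance = 0,
         sum_entropy = 0, asm = 0, contrast = 0, dissimilarity = 0,
         inverse_difference = 0, inverse_difference_norm = 0,
         inverse_difference_moment = 0, inverse_difference_moment_norm = 0,
         inverse_variance = 0, correlation = 0, autocorrelation = 0,
         cluster_tendency = 0, cluster_shade = 0, cluster_prominence = 0,
         info_corr_1 = 0, info_corr_2 = 0)
  pd <- numeric(ng)          # |i-j| = 0..ng-1 at index k+1
  ps <- numeric(2 * ng - 1)  # i+j = 2..2ng at index i+j-1
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    f["joint_variance"] <- f["joint_variance"] + (i - mu)^2 * p
    if (p > 0) f["joint_entropy"] <- f["joint_entropy"] - p * log2(p)
    f["asm"] <- f["asm"] + p^2
    f["contrast"] <- f["contrast"] + (i - j)^2 * p
    f["dissimilarity"] <- f["dissimilarity"] + abs(i - j) * p
    f["inverse_difference"] <- f["inverse_difference"] + p / (1 + abs(i - j))
    f["inverse_difference_norm"] <- f["inverse_difference_norm"] +
      p / (1 + abs(i - j) / ng)
    f["inverse_difference_moment"] <- f["inverse_difference_moment"] +
      p / (1 + (i - j)^2)
    f["inverse_difference_moment_norm"] <- f["inverse_difference_moment_norm"] +
      p / (1 + (i - j)^2 / ng^2)
    if (i != j) f["inverse_variance"] <- f["inverse_variance"] + p / (i - j)^2
    f["autocorrelation"] <- f["autocorrelation"] + i * j * p
    f["cluster_tendency"] <- f["cluster_tendency"] + (i + j - 2 * mu)^2 * p
    f["cluster_shade"] <- f["cluster_shade"] + (i + j - 2 * mu)^3 * p
    f["cluster_prominence"] <- f["cluster_prominence"] + (i + j - 2 * mu)^4 * p
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p
    ps[i + j - 1] <- ps[i + j - 1] + p
  }
  da <- sum((0:(ng - 1)) * pd)
  f["difference_average"] <- da
  f["difference_variance"] <- sum(((0:(ng - 1)) - da)^2 * pd)
  f["difference_entropy"] <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  sa <- sum((2:(2 * ng)) * ps)
  f["sum_average"] <- sa
  f["sum_variance"] <- sum(((2:(2 * ng)) - sa)^2 * ps)
  f["sum_entropy"] <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  sig2 <- sum((1:ng - sum((1:ng) * px))^2 * px)
  f["correlation"] <- if (sig2 > 0) (f[["autocorrelation"]] - mu^2) / sig2 else 1
  hxy <- f[["joint_entropy"]]
  hxy1 <- 0; hxy2 <- 0; hx <- 0
  for (i in 1:ng) {
    if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
    for (j in 1:ng) {
      pij <- px[i] * px[j]
      if (pij > 0) {
        hxy1 <- hxy1 - P[i, j] * log2(pij)
        hxy2 <- hxy2 - pij * log2(pij)
      }
    }
  }
  f["info_corr_1"] <- if (hx > 0) (hxy - hxy1) / hx else 0
  f["info_corr_2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  f
}

bf_glcm_features <- function(lev, ng) {
  acc <- NULL; nd <- 0
  for (r in seq_len(nrow(bf_dirs))) {
    P <- bf_glcm_matrix(lev, bf_dirs[r, ], ng)
    if (is.null(P)) next
    fr <- bf_glcm_features_one(P)
    acc <- if (is.null(acc)) fr else acc + fr
    nd <- nd + 1
  }
  out <- acc / nd
  names(out) <- paste0("glcm.", names(out))
  out
}

## ---- GLRLM ----

bf_glrlm_matrix <- function(lev, d, ng) {
  dm <- dim(lev)
  runs <- list()
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    if (bf_inside(c(x, y, z) - d, dm)) next  # not a line start
    # walk the line
    p <- c(x, y, z)
    cur_lev <- 0L; cur_len <- 0L
    while (bf_inside(p, dm)) {
      l <- lev[p[1], p[2], p[3]]
      l <- if (is.na(l)) 0L else l
      if (l == cur_lev) cur_len <- cur_len + 1L
      else {
        if (cur_lev > 0) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
        cur_lev <- l; cur_len <- 1L
      }
      p <- p + d
    }
    if (cur_lev > 0) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
  }
  if (length(runs) == 0) return(NULL)
  rl <- do.call(rbind, runs)
  R <- matrix(0, ng, max(rl[, 2]))
  for (k in seq_len(nrow(rl))) R[rl[k, 1], rl[k, 2]] <- R[rl[k, 1], rl[k, 2]] + 1
  R
}

bf_rlm_features <- function(R, n_vox) {
  ns <- sum(R)
  out <- c(sre = 0, lre = 0, lglre = 0, hglre = 0, srlgle = 0, srhgle = 0,
           lrlgle = 0, lrhgle = 0, gln = 0, glnn = 0, rln = 0, rlnn = 0,
           rp = ns / n_vox, glv = 0, rlv = 0, re = 0)
  mu_i <- 0; mu_j <- 0
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    mu_i <- mu_i + i * R[i, j] / ns
    mu_j <- mu_j + j * R[i, j] / ns
  }
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    c_ <- R[i, j]
    if (c_ == 0) next
    p <- c_ / ns
    out["sre"] <- out["sre"] + c_ / j^2 / ns
    out["lre"] <- out["lre"] + c_ * j^2 / ns
    out["lglre"] <- out["lglre"] + c_ / i^2 / ns
    out["hglre"] <- out["hglre"] + c_ * i^2 / ns
    out["srlgle"] <- out["srlgle"] + c_ / (i^2 * j^2) / ns
    out["srhgle"] <- out["srhgle"] + c_ * i^2 / j^2 / ns
    out["lrlgle"] <- out["lrlgle"] + c_ * j^2 / i^2 / ns
    out["lrhgle"] <- out["lrhgle"] + c_ * i^2 * j^2 / ns
    out["glv"] <- out["glv"] + (i - mu_i)^2 * p
    out["rlv"] <- out["rlv"] + (j - mu_j)^2 * p
    out["re"] <- out["re"] - p * log2(p)
  }
  for (i in seq_len(nrow(R))) out["gln"] <- out["gln"] + sum(R[i, ])^2 / ns
  for (j in seq_len(ncol(R))) out["rln"] <- out["rln"] + sum(R[, j])^2 / ns
  out["glnn"] <- out["gln"] / ns
  out["rlnn"] <- out["rln"] / ns
  out
}

bf_glrlm_features <- function(lev, ng) {
  n_vox <- sum(!is.na(lev))
  acc <- NULL; nd <- 0
  for (r in seq_len(nrow(bf_dirs))) {
    R <- bf_glrlm_matrix(lev, bf_dirs[r, ], ng)
    if (is.null(R)) next
    fr <- bf_rlm_features(R, n_vox)
    acc <- if (is.null(acc)) fr else acc + fr
    nd <- nd + 1
  }
  out <- acc / nd
  names(out) <- paste0("glrlm.", names(out))
  out
}

## ---- zones (GLSZM / GLDZM) ----

bf_zones <- function(lev) {
  dm <- dim(lev)
  seen <- array(FALSE, dm)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  zones <- list()
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    if (is.na(lev[x, y, z]) || seen[x, y, z]) next
    l <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    members <- list()
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      members[[length(members) + 1]] <- p
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (!bf_inside(q, dm)) next
        if (seen[q[1], q[2], q[3]]) next
        lq <- lev[q[1], q[2], q[3]]
        if (is.na(lq) || lq != l) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- list(level = l, voxels = members)
  }
  zones
}

bf_zone_features <- function(lev_s, attr_s, n_vox) {
  nz <- length(lev_s)
  out <- c(small = 0, large = 0, lgl = 0, hgl = 0, small_lgl = 0,
           small_hgl = 0, large_lgl = 0, large_hgl = 0, gln = 0, glnn = 0,
           zn = 0, znn = 0, zp = nz / n_vox, glv = 0, zv = 0, ze = 0)
  mu_i <- mean(lev_s); mu_j <- mean(attr_s)
  for (k in seq_len(nz)) {
    i <- lev_s[k]; j <- attr_s[k]
    out["small"] <- out["small"] + 1 / j^2 / nz
    out["large"] <- out["large"] + j^2 / nz
    out["lgl"] <- out["lgl"] + 1 / i^2 / nz
    out["hgl"] <- out["hgl"] + i^2 / nz
    out["small_lgl"] <- out["small_lgl"] + 1 / (i^2 * j^2) / nz
    out["small_hgl"] <- out["small_hgl"] + i^2 / j^2 / nz
    out["large_lgl"] <- out["large_lgl"] + j^2 / i^2 / nz
    out["large_hgl"] <- out["large_hgl"] + i^2 * j^2 / nz
    out["glv"] <- out["glv"] + (i - mu_i)^2 / nz
    out["zv"] <- out["zv"] + (j - mu_j)^2 / nz
  }
  for (i in unique(lev_s)) out["gln"] <- out["gln"] + sum(lev_s == i)^2 / nz
  for (j in unique(attr_s)) out["zn"] <- out["zn"] + sum(attr_s == j)^2 / nz
  out["glnn"] <- out["gln"] / nz
  out["znn"] <- out["zn"] / nz
  cnt <- table(paste(lev_s, attr_s))
  p <- as.numeric(cnt) / nz
  out["ze"] <- -sum(p * log2(p))
  out
}

bf_glszm_features <- function(lev, ng) {
  zs <- bf_zones(lev)
  f <- bf_zone_features(vapply(zs, `[[`, numeric(1), "level"),
                        vapply(zs, function(z) length(z$voxels), numeric(1)),
                        sum(!is.na(lev)))
  names(f) <- paste0("glszm.", c("sze", "lze", "lglze", "hglze", "szlgle",
                                 "szhgle", "lzlgle", "lzhgle", "gln", "glnn",
                                 "zsn", "zsnn", "zp", "glv", "zv", "ze"))
  f
}

# distance of one voxel to the mask border: BFS through the mask
# (6-connectivity); border voxels (adjacent to outside/edge) have distance 1
bf_border_distance <- function(mask, start) {
  dm <- dim(mask)
  ax <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  is_border <- function(p) {
    for (r in 1:6) {
      q <- p + ax[r, ]
      if (!bf_inside(q, dm) || !mask[q[1], q[2], q[3]]) return(TRUE)
    }
    FALSE
  }
  seen <- array(FALSE, dm)
  queue <- list(list(p = start, d = 1))
  seen[start[1], start[2], start[3]] <- TRUE
  while (length(queue) > 0) {
    node <- queue[[1]]; queue <- queue[-1]
    if (is_border(node$p)) return(node$d)
    for (r in 1:6) {
      q <- node$p + ax[r, ]
      if (!bf_inside(q, dm) || !mask[q[1], q[2], q[3]]) next
      if (seen[q[1], q[2], q[3]]) next
      seen[q[1], q[2], q[3]] <- TRUE
      queue[[length(queue) + 1]] <- list(p = q, d = node$d + 1)
    }
  }
  stop("no border found")
}

bf_gldzm_features <- function(lev, ng) {
  mask <- !is.na(lev)
  zs <- bf_zones(lev)
  zd <- vapply(zs, function(z) {
    min(vapply(z$voxels, function(p) bf_border_distance(mask, p), numeric(1)))
  }, numeric(1))
  f <- bf_zone_features(vapply(zs, `[[`, numeric(1), "level"), zd, sum(mask))
  names(f) <- paste0("gldzm.", c("sde", "lde", "lglze", "hglze", "sdlgle",
                                 "sdhgle", "ldlgle", "ldhgle", "gln", "glnn",
                                 "zdn", "zdnn", "zp", "glv", "zv", "ze"))
  f
}

## ---- NGTDM / GLDM ----

bf_ngtdm_features <- function(lev, ng) {
  dm <- dim(lev)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  Ls <- c(); As <- c()
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    l <- lev[x, y, z]
    if (is.na(l)) next
    nb <- c()
    for (r in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[r, ]
      if (!bf_inside(q, dm)) next
      lq <- lev[q[1], q[2], q[3]]
      if (!is.na(lq)) nb <- c(nb, lq)
    }
    if (length(nb) == 0) next
    Ls <- c(Ls, l); As <- c(As, mean(nb))
  }
  nv <- length(Ls)
  n_i <- sapply(1:ng, function(i) sum(Ls == i))
  s_i <- sapply(1:ng, function(i) if (n_i[i] > 0) sum(abs(i - As[Ls == i])) else 0)
  p_i <- n_i / nv
  pres <- which(n_i > 0)
  np <- length(pres)
  coarseness <- if (sum(p_i * s_i) > 0) 1 / sum(p_i * s_i) else 1e6
  contrast <- 0; busy_den <- 0; complexity <- 0; strength <- 0
  if (np > 1) {
    for (i in pres) for (j in pres) {
      contrast <- contrast + p_i[i] * p_i[j] * (i - j)^2
      busy_den <- busy_den + abs(i * p_i[i] - j * p_i[j])
      complexity <- complexity + abs(i - j) *
        (p_i[i] * s_i[i] + p_i[j] * s_i[j]) / (p_i[i] + p_i[j])
      strength <- strength + (p_i[i] + p_i[j]) * (i - j)^2
    }
    contrast <- contrast / (np * (np - 1)) * sum(s_i) / nv
    complexity <- complexity / nv
    strength <- if (sum(s_i) > 0) strength / sum(s_i) else 0
  }
  busyness <- if (np > 1 && busy_den > 0) sum(p_i * s_i) / busy_den else 0
  out <- c(coarseness = coarseness, contrast = contrast,
           busyness = busyness, complexity = complexity, strength = strength)
  names(out) <- paste0("ngtdm.", names(out))
  out
}

bf_gldm_features <- function(lev, ng) {
  dm <- dim(lev)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  Ls <- c(); Ds <- c()
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    l <- lev[x, y, z]
    if (is.na(l)) next
    dep <- 0L
    for (r in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[r, ]
      if (!bf_inside(q, dm)) next
      lq <- lev[q[1], q[2], q[3]]
      if (!is.na(lq) && lq == l) dep <- dep + 1L
    }
    Ls <- c(Ls, l); Ds <- c(Ds, dep + 1L)
  }
  nv <- length(Ls)
  key <- paste(Ls, Ds)
  cnt <- table(key)
  p <- as.numeric(cnt) / nv
  mu_j <- mean(Ds)
  sde <- sum(1 / Ds^2) / nv
  lde <- sum(Ds^2) / nv
  dnn <- sum(sapply(unique(Ds), function(j) sum(Ds == j)^2)) / nv^2
  dv <- mean((Ds - mu_j)^2)
  de <- -sum(p * log2(p))
  out <- c(sde = sde, lde = lde, dnn = dnn, dv = dv, de = de)
  names(out) <- paste0("gldm.", names(out))
  out
}

## ---- ReliefF ----

bf_relieff <- function(X, y, k) {
  X <- as.matrix(X)
  y <- as.factor(y)
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  scl <- ifelse(rng > 0, rng, 1)
  Xs <- X
  for (f in 1:p) Xs[, f] <- (X[, f] - min(X[, f])) / scl[f]
  Xs[, rng == 0] <- 0
  priors <- table(y) / n
  W <- numeric(p)
  for (i in 1:n) {
    d <- numeric(n)
    for (j in 1:n) d[j] <- sum(abs(Xs[i, ] - Xs[j, ]))
    for (f in 1:p) {
      # hits
      pool <- setdiff(which(y == y[i]), i)
      if (length(pool) == 0) next
      kh <- min(k, length(pool))
      hits <- pool[order(d[pool], pool)][1:kh]
      W[f] <- W[f] - mean(abs(Xs[hits, f] - Xs[i, f])) / n
      for (cl in levels(y)) {
        if (cl == y[i]) next
        mp <- which(y == cl)
        if (length(mp) == 0) next
        km <- min(k, length(mp))
        miss <- mp[order(d[mp], mp)][1:km]
        W[f] <- W[f] + priors[[cl]] / (1 - priors[[as.character(y[i])]]) *
          mean(abs(Xs[miss, f] - Xs[i, f])) / n
      }
    }
  }
  stats::setNames(W, colnames(X))
}

## ---- misc fixtures ----

# quick SUV scan_record around an array
make_suv_record <- function(img, mask = NULL, spacing = 1,
                            arm = "preclinical", subject = "T1",
                            timepoint = "BL") {
  img <- if (length(dim(img)) == 3) img else array(img, c(dim(img), 1))
  if (is.null(mask)) mask <- array(TRUE, dim(img))
  scan_record(subject, img, mask, spacing, arm = arm, timepoint = timepoint,
              units = "SUV", injected_dose_bq = 1e6, body_weight_g = 25)
}

# random small level grid with full mask
random_toy_levels <- function(dm, ng, seed) {
  set.seed(seed)
  array(sample.int(ng, prod(dm), replace = TRUE), dm)
}
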