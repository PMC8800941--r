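# Internal 3D array helpers shared by the phantom generator, SUV peak search,
# and the texture-matrix builders. All grids are dense base-R arrays indexed
# [x, y, z] with world coordinates given by voxel spacing only.

# The 13 unique 3D directions (26-neighbourhood up to sign).
DIRECTIONS_3D <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
)

# All 26 neighbour offsets.
offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# Shift an array so that out[i] = a[i + d]; positions falling outside the
# grid become `fill`.
shift3 <- function(a, d, fill = NA_real_) {
  dm <- dim(a)
  out <- array(fill, dm)
  idx_dst <- idx_src <- vector("list", 3L)
  for (k in 1:3) {
    n <- dm[k]
    dk <- d[k]
    if (abs(dk) >= n) return(out)
    if (dk >= 0) {
      idx_dst[[k]] <- seq_len(n - dk)
      idx_src[[k]] <- seq_len(n - dk) + dk
    } else {
      idx_dst[[k]] <- seq_len(n + dk) - dk
      idx_src[[k]] <- seq_len(n + dk)
    }
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Zero-padded 'same' FFT convolution of two 3D arrays (kernel dims odd).
conv3d <- function(a, k) {
  da <- dim(a)
  dk <- dim(k)
  dp <- da + dk - 1L
  A <- array(0, dp)
  A[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- a
  K <- array(0, dp)
  K[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  C <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / prod(dp)
  off <- (dk - 1L) %/% 2L
  C[off[1] + seq_len(da[1]), off[2] + seq_len(da[2]), off[3] + seq_len(da[3])]
}

# Separable Gaussian kernel truncated at 3 sigma (sigma in voxels, per axis).
gaussian_kernel3 <- function(sigma_vox) {
  sigma_vox <- pmax(rep(sigma_vox, length.out = 3), 1e-6)
  axes <- lapply(sigma_vox, function(s) {
    r <- max(1L, ceiling(3 * s))
    x <- seq(-r, r)
    w <- exp(-x^2 / (2 * s^2))
    w / sum(w)
  })
  k <- outer(outer(axes[[1]], axes[[2]]), axes[[3]])
  array(k, dim = c(length(axes[[1]]), length(axes[[2]]), length(axes[[3]])))
}

# Logical sphere kernel of a given physical radius on the voxel grid.
sphere_kernel <- function(radius_mm, spacing_mm) {
  r_vox <- ceiling(radius_mm / spacing_mm)
  cx <- lapply(1:3, function(k) seq(-r_vox[k], r_vox[k]) * spacing_mm[k])
  d2 <- outer(outer(cx[[1]]^2, cx[[2]]^2, `+`), cx[[3]]^2, `+`)
  array(d2 <= radius_mm^2, dim = dim(d2))
}

# City-block distance of each in-mask voxel to the mask border (border voxels
# have distance 1; voxels next to the image edge also count as border).
distance_map_cityblock <- function(mask) {
  dm <- dim(mask)
  dist <- array(NA_real_, dm)
  outside <- !mask
  axes6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  # voxels adjacent (6-conn) to outside or to the image edge
  adj_out <- array(FALSE, dm)
  for (i in seq_len(nrow(axes6))) {
    nb <- shift3(outside * 1, axes6[i, ], fill = 1)
    adj_out <- adj_out | (nb > 0)
  }
  frontier <- mask & adj_out
  d <- 1
  while (any(frontier)) {
    dist[frontier] <- d
    assigned <- !is.na(dist)
    nxt <- array(FALSE, dm)
    for (i in seq_len(nrow(axes6))) {
      nb <- shift3(assigned * 1, axes6[i, ], fill = 0)
      nxt <- nxt | (nb > 0)
    }
    frontier <- mask & !assigned & nxt
    d <- d + 1
  }
  dist
}

# Connected components of same-level in-mask voxels (26-connectivity).
# Returns, per zone: its gray level and size, plus a voxel->zone id map.
label_zones <- function(levels_arr, mask) {
  dm <- dim(levels_arr)
  ids <- which(mask)
  n <- length(ids)
  vox_index <- array(0L, dm)
  vox_index[ids] <- seq_len(n)
  edges <- vector("list", nrow(DIRECTIONS_3D))
  for (i in seq_len(nrow(DIRECTIONS_3D))) {
    nb_lev <- shift3(levels_arr, DIRECTIONS_3D[i, ])
    nb_idx <- shift3(vox_index, DIRECTIONS_3D[i, ], fill = 0L)
    ok <- mask & !is.na(nb_lev) & nb_idx > 0 & nb_lev == levels_arr
    from <- vox_index[ok]
    to <- nb_idx[ok]
    edges[[i]] <- cbind(from, to)
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(em) && nrow(em) > 0) {
    g <- igraph::add_edges(g, t(em))
  }
  comp <- igraph::components(g)
  zone_of_voxel <- comp$membership
  zone_level <- as.integer(tapply(levels_arr[ids], zone_of_voxel, function(x) x[1]))
  zone_size <- as.integer(comp$csize)
  list(zone_level = zone_level, zone_size = zone_size,
       membership = zone_of_voxel, voxel_ids = ids)
}

# Crop image+mask to the mask bounding box with a 1-voxel pad (texture
# matrices only see the tumor; cropping keeps the shifts cheap).
crop_to_mask <- function(image, mask, pad = 1L) {
  stopifnot(any(mask))
  w <- which(mask, arr.ind = TRUE)
  dm <- dim(mask)
  lo <- pmax(apply(w, 2, min) - pad, 1L)
  hi <- pmin(apply(w, 2, max) + pad, dm)
  list(image = image[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       mask = mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
}

# Deterministic 32-bit sub-seed from a base seed and string salt.
derive_seed <- function(seed, ...) {
  salt <- paste(..., collapse = "|")
  h <- 0
  for (ch in utf8ToInt(salt)) h <- (h * 131 + ch) %% 1000000007
  as.integer((abs(seed) * 7919 + h) %% 2147483629)
}
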