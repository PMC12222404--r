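# Internal array helpers shared across modules. All operate on plain 3D
# arrays; volume3d wrappers live in volume.R.

# Shift an array by integer offsets, filling vacated voxels with `fill`.
shift_array <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (length(sx) < 1 || length(sy) < 1 || length(sz) < 1) return(out)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

# 6-neighbour (face-connected) binary erosion / dilation; the structuring
# element is the radius-1 ball in voxel metric (a 3D cross).
erode6 <- function(mask) {
  m <- mask
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    m <- m & shift_array(mask, s[1], s[2], s[3], fill = FALSE)
  }
  m
}

dilate6 <- function(mask) {
  m <- mask
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    m <- m | shift_array(mask, s[1], s[2], s[3], fill = FALSE)
  }
  m
}

close6 <- function(mask) erode6(dilate6(mask))

# Separable 1D Gaussian convolution along one array dimension with zero
# padding (callers renormalise when conservation is required).
conv_dim_gauss <- function(a, sigma_vox, dim_idx) {
  if (sigma_vox <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  d <- dim(a)
  out <- array(0, dim = d)
  for (i in seq_along(k)) {
    off <- (-r:r)[i]
    s <- c(0L, 0L, 0L)
    s[dim_idx] <- off
    out <- out + k[i] * shift_array(a, s[1], s[2], s[3], fill = 0)
  }
  out
}

# 3D Gaussian blur, sigma given in voxels per axis.
gaussian_blur3 <- function(a, sigma_vox) {
  if (length(sigma_vox) == 1) sigma_vox <- rep(sigma_vox, 3)
  for (ax in 1:3) a <- conv_dim_gauss(a, sigma_vox[ax], ax)
  a
}

# Constant-preserving blur: divide by the blur of an all-ones field so a
# uniform input maps to itself exactly (used for regression features).
gaussian_blur3_norm <- function(a, sigma_vox) {
  num <- gaussian_blur3(a, sigma_vox)
  den <- gaussian_blur3(array(1, dim(a)), sigma_vox)
  num / den
}

# Box-filter sums over full (2r+1)^3 windows; returns an array of dimension
# dim(a) - 2r ("valid" windows only). Used by the SSIM implementation.
box_sum_valid <- function(a, r) {
  w <- 2L * r + 1L
  d <- dim(a)
  stopifnot(all(d >= w))
  for (ax in 1:3) {
    n <- dim(a)[ax] - w + 1L
    idx <- function(off) {
      i <- list(TRUE, TRUE, TRUE)
      i[[ax]] <- (1L + off):(n + off)
      i
    }
    acc <- do.call(`[`, c(list(a), idx(0L), drop = FALSE))
    for (off in seq_len(w - 1L)) {
      acc <- acc + do.call(`[`, c(list(a), idx(off), drop = FALSE))
    }
    a <- acc
  }
  a
}

# Iterated-erosion depth (in erosion passes) of a binary support; a cheap
# monotone proxy for distance-to-surface used as a regression feature.
erosion_depth <- function(mask, max_iter = 200L) {
  depth <- array(0, dim(mask))
  cur <- mask
  it <- 0L
  while (any(cur) && it < max_iter) {
    depth <- depth + cur
    cur <- erode6(cur)
    it <- it + 1L
  }
  depth
}

`%||%` <- function(a, b) if (is.null(a)) b else a
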