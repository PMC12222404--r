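# Independent oracles used across the suite. These deliberately use direct,
# unoptimised formulations (explicit loops, exhaustive enumeration) so they
# share no code path with the package implementations they check.

# Exhaustive brute-force 3D gamma: for every evaluated voxel, scan the full
# refined search neighbourhood, trilinearly interpolating the evaluated map
# with an inline 8-corner formula. No early termination, no sorting.
bruteforce_gamma <- function(ref, evalv, spacing, dta, dd_frac, dnorm,
                             refine = 3L, cap = 2) {
  d <- dim(ref)
  radius <- cap * dta
  rx <- floor(radius * refine / spacing[1])
  ry <- floor(radius * refine / spacing[2])
  rz <- floor(radius * refine / spacing[3])
  if (length(dnorm) == 1) dnorm <- array(dnorm, d)
  g2 <- array(Inf, d)
  vx <- slice.index(ref, 1) - 1
  vy <- slice.index(ref, 2) - 1
  vz <- slice.index(ref, 3) - 1
  for (i in -rx:rx) for (j in -ry:ry) for (k in -rz:rz) {
    dx <- i / refine; dy <- j / refine; dz <- k / refine
    dist2 <- (dx * spacing[1])^2 + (dy * spacing[2])^2 + (dz * spacing[3])^2
    if (dist2 > radius^2) next
    px <- vx + dx; py <- vy + dy; pz <- vz + dz
    valid <- px >= 0 & px <= d[1] - 1 & py >= 0 & py <= d[2] - 1 &
      pz >= 0 & pz <= d[3] - 1
    if (!any(valid)) next
    i0 <- pmax(pmin(floor(px), d[1] - 2), 0)
    j0 <- pmax(pmin(floor(py), d[2] - 2), 0)
    k0 <- pmax(pmin(floor(pz), d[3] - 2), 0)
    fx <- px - i0; fy <- py - j0; fz <- pz - k0
    at <- function(a, b, cc) evalv[1 + a + d[1] * (b + d[2] * cc)]
    de <- (1 - fx) * (1 - fy) * (1 - fz) * at(i0, j0, k0) +
      fx * (1 - fy) * (1 - fz) * at(pmin(i0 + 1, d[1] - 1), j0, k0) +
      (1 - fx) * fy * (1 - fz) * at(i0, pmin(j0 + 1, d[2] - 1), k0) +
      fx * fy * (1 - fz) * at(pmin(i0 + 1, d[1] - 1), pmin(j0 + 1, d[2] - 1), k0) +
      (1 - fx) * (1 - fy) * fz * at(i0, j0, pmin(k0 + 1, d[3] - 1)) +
      fx * (1 - fy) * fz * at(pmin(i0 + 1, d[1] - 1), j0, pmin(k0 + 1, d[3] - 1)) +
      (1 - fx) * fy * fz * at(i0, pmin(j0 + 1, d[2] - 1), pmin(k0 + 1, d[3] - 1)) +
      fx * fy * fz * at(pmin(i0 + 1, d[1] - 1), pmin(j0 + 1, d[2] - 1),
                        pmin(k0 + 1, d[3] - 1))
    denom <- dd_frac * dnorm
    dterm <- ifelse(denom > 0, ((de - ref) / denom)^2,
                    ifelse(de == ref, 0, Inf))
    cand <- dist2 / dta^2 + dterm
    cand[!valid] <- Inf
    g2 <- pmin(g2, cand)
  }
  pmin(sqrt(g2), cap)
}

# Direct per-window SSIM: explicit loop over every full window, sample
# (n-1) variances/covariance.
bruteforce_ssim <- function(a, b, window = 7L, k1 = 0.01, k2 = 0.03) {
  d <- dim(a)
  L <- diff(range(b))
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  vals <- c()
  for (i in seq_len(d[1] - window + 1)) {
    for (j in seq_len(d[2] - window + 1)) {
      for (k in seq_len(d[3] - window + 1)) {
        wa <- a[i:(i + window - 1), j:(j + window - 1), k:(k + window - 1)]
        wb <- b[i:(i + window - 1), j:(j + window - 1), k:(k + window - 1)]
        ma <- mean(wa); mb <- mean(wb)
        va <- var(as.numeric(wa)); vb <- var(as.numeric(wb))
        cab <- cov(as.numeric(wa), as.numeric(wb))
        vals <- c(vals, ((2 * ma * mb + c1) * (2 * cab + c2)) /
                    ((ma^2 + mb^2 + c1) * (va + vb + c2)))
      }
    }
  }
  mean(vals)
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of ranks.
enumerate_ranksum <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mu <- m * n / 2
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu))
  list(u = u_obs, p = p)
}

# Small random dose volume for property tests.
random_dose_array <- function(d = c(10, 10, 10), max_gy = 100) {
  array(runif(prod(d), 0, max_gy), dim = d)
}

# meta_tol: NIfTI-1 headers store spacing/origin as 32-bit floats, so grid
# metadata round-trips at single precision; the MetaImage text header keeps
# full double precision.
expect_volumes_equal <- function(a, b, tol = 1e-12, meta_tol = 1e-12) {
  expect_equal(dim(a$values), dim(b$values))
  expect_lt(max(abs(a$values - b$values)), tol)
  expect_equal(a$spacing, b$spacing, tolerance = meta_tol)
  expect_equal(a$origin, b$origin, tolerance = meta_tol)
}

# Small phantom recipe used by phantom/engine tests.
test_recipe <- function(shape = c(32L, 32L, 32L), seed = 1L, ...) {
  phantom_recipe(shape = shape, seed = seed, ...)
}
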