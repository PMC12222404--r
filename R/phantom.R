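#' Digital-phantom recipe
#'
#' Parameterises a liver-centred activity distribution on a SPECT-like grid:
#' ellipsoidal body, liver and organs at risk, spherical tumour(s) inside
#' the liver, a tumour:liver uptake ratio above one (tumour-avid, as in
#' glass-microsphere SIRT), and an optional lung-shunt background. All
#' geometry is given in fractions of the grid extent so recipes scale
#' between the acquisition-sized 128^3 grid and smaller desk grids.
#'
#' @param shape grid dimensions (default `c(128, 128, 128)`).
#' @param spacing_mm isotropic voxel size (default 4.795 mm).
#' @param body,liver,lungs,kidneys,stomach ellipsoids as
#'   `list(center = , radii = )` in fractional grid coordinates (lungs and
#'   kidneys are mirrored pairs).
#' @param tumours list of spheres `list(center = , radius_mm = )`; centres
#'   fractional, radii in mm.
#' @param uptake_ratio tumour : normal-liver activity-concentration ratio
#'   (> 1; default 5).
#' @param liver_conc normal-liver activity concentration (arbitrary units).
#' @param body_background fraction of `liver_conc` outside the liver.
#' @param lung_shunt fraction of `liver_conc` in the lungs (default 0.02).
#' @param injected_activity_gbq net injected activity (default 2.0 GBq).
#' @param total_counts expected total detected counts used to scale count
#'   maps before Poisson noise (default 2e6).
#' @param seed integer seed for stochastic components (Poisson noise).
#' @return an object of class `phantom_recipe`.
#' @export
phantom_recipe <- function(shape = c(128L, 128L, 128L), spacing_mm = 4.795,
                           body = list(center = c(0.50, 0.50, 0.50),
                                       radii = c(0.44, 0.34, 0.48)),
                           liver = list(center = c(0.63, 0.46, 0.48),
                                        radii = c(0.20, 0.17, 0.22)),
                           tumours = list(list(center = c(0.68, 0.44, 0.50),
                                               radius_mm = 30)),
                           lungs = list(center = c(0.50, 0.50, 0.86),
                                        radii = c(0.13, 0.12, 0.10),
                                        offset = 0.17),
                           kidneys = list(center = c(0.50, 0.68, 0.30),
                                          radii = c(0.06, 0.05, 0.08),
                                          offset = 0.16),
                           stomach = list(center = c(0.32, 0.42, 0.52),
                                          radii = c(0.09, 0.07, 0.09)),
                           uptake_ratio = 5, liver_conc = 1,
                           body_background = 0.01, lung_shunt = 0.02,
                           injected_activity_gbq = 2.0,
                           total_counts = 2e6, seed = 1L) {
  if (uptake_ratio <= 1)
    stop("phantom_recipe: uptake_ratio must exceed 1 (tumour-avid)", call. = FALSE)
  stopifnot(length(shape) == 3, all(shape >= 8), spacing_mm > 0,
            injected_activity_gbq > 0, total_counts > 0)
  structure(list(shape = as.integer(shape), spacing_mm = spacing_mm,
                 body = body, liver = liver, tumours = tumours,
                 lungs = lungs, kidneys = kidneys, stomach = stomach,
                 uptake_ratio = uptake_ratio, liver_conc = liver_conc,
                 body_background = body_background, lung_shunt = lung_shunt,
                 injected_activity_gbq = injected_activity_gbq,
                 total_counts = total_counts, seed = as.integer(seed)),
            class = "phantom_recipe")
}

#' Image-degradation model for synthetic SPECT states
#'
#' Stand-in physics for the reconstruction-time corrections: depth-dependent
#' photon attenuation (Beer-Lambert along a fan of in-plane ray directions
#' spanning 180 degrees, as acquired) and energy-window-trapped scatter (a
#' count-conserving broad Gaussian redistribution of a fixed fraction of
#' counts; clinically 30-40% of photopeak-window photons are scattered).
#'
#' @param mu_soft,mu_lung,mu_bone linear attenuation coefficients, mm^-1
#'   (broad-spectrum bremsstrahlung effective values).
#' @param n_projection_dirs number of in-plane ray directions over 180
#'   degrees (default 16; 64 mirrors the acquisition).
#' @param scatter_fraction fraction of counts redistributed by scatter,
#'   in [0, 1) (default 0.35).
#' @param scatter_kernel_fwhm_mm FWHM of the scatter kernel (default 30 mm).
#' @param poisson_noise apply Poisson counting noise to count maps.
#' @return an object of class `degradation_model`.
#' @export
degradation_model <- function(mu_soft = 0.011, mu_lung = 0.003,
                              mu_bone = 0.017, n_projection_dirs = 16L,
                              scatter_fraction = 0.35,
                              scatter_kernel_fwhm_mm = 30,
                              poisson_noise = TRUE) {
  if (scatter_fraction < 0 || scatter_fraction >= 1)
    stop("degradation_model: scatter_fraction must be in [0, 1)", call. = FALSE)
  if (mu_soft < 0 || mu_lung < 0 || mu_bone < 0)
    stop("degradation_model: attenuation coefficients must be >= 0", call. = FALSE)
  stopifnot(n_projection_dirs >= 1, scatter_kernel_fwhm_mm > 0)
  structure(list(mu_soft = mu_soft, mu_lung = mu_lung, mu_bone = mu_bone,
                 n_projection_dirs = as.integer(n_projection_dirs),
                 scatter_fraction = scatter_fraction,
                 scatter_kernel_fwhm_mm = scatter_kernel_fwhm_mm,
                 poisson_noise = poisson_noise),
            class = "degradation_model")
}

ellipsoid_mask <- function(shape, center_frac, radii_frac) {
  cx <- center_frac * shape
  rx <- pmax(radii_frac * shape, 1e-9)
  xi <- (seq_len(shape[1]) - 0.5 - cx[1]) / rx[1]
  yi <- (seq_len(shape[2]) - 0.5 - cx[2]) / rx[2]
  zi <- (seq_len(shape[3]) - 0.5 - cx[3]) / rx[3]
  outer(outer(xi^2, yi^2, `+`), zi^2, `+`) <= 1
}

sphere_mask <- function(shape, spacing_mm, center_frac, radius_mm) {
  if (radius_mm <= 0) return(array(FALSE, shape))
  r_frac <- radius_mm / (shape * spacing_mm)
  ellipsoid_mask(shape, center_frac, r_frac)
}

#' Build a digital phantom
#'
#' Produces a piecewise-constant true activity distribution, the full
#' segmentation set (body, WL, WNL, tumour, lungs, kidneys, stomach) and the
#' attenuation-coefficient map.
#'
#' @param recipe a [phantom_recipe].
#' @param model a [degradation_model] (for the attenuation coefficients in
#'   the mu map).
#' @return list with `true_activity` ([volume3d], arbitrary concentration
#'   units), `masks` ([segmentation_set]) and `mu_map` ([volume3d], mm^-1).
#' @export
build_phantom <- function(recipe, model = degradation_model()) {
  stopifnot(inherits(recipe, "phantom_recipe"),
            inherits(model, "degradation_model"))
  sh <- recipe$shape
  sp <- rep(recipe$spacing_mm, 3)
  body <- ellipsoid_mask(sh, recipe$body$center, recipe$body$radii)
  liver <- ellipsoid_mask(sh, recipe$liver$center, recipe$liver$radii) & body
  if (!any(liver)) stop("build_phantom: liver lies outside the body", call. = FALSE)
  tumour <- array(FALSE, sh)
  for (tu in recipe$tumours) {
    tm <- sphere_mask(sh, recipe$spacing_mm, tu$center, tu$radius_mm)
    if (any(tm) && !any(tm & liver))
      stop("build_phantom: a tumour lies entirely outside the liver", call. = FALSE)
    tumour <- tumour | (tm & liver)
  }
  mirror <- function(spec) {
    c1 <- spec$center; c1[1] <- spec$center[1] - spec$offset
    c2 <- spec$center; c2[1] <- spec$center[1] + spec$offset
    (ellipsoid_mask(sh, c1, spec$radii) | ellipsoid_mask(sh, c2, spec$radii)) & body
  }
  lungs <- mirror(recipe$lungs) & !liver
  kidneys <- mirror(recipe$kidneys) & !liver
  stomach <- ellipsoid_mask(sh, recipe$stomach$center, recipe$stomach$radii) &
    body & !liver & !lungs
  masks <- segmentation_set(list(body = body, wl = liver, tumour = tumour,
                                 lungs = lungs, kidneys = kidneys,
                                 stomach = stomach),
                            spacing = sp, origin = c(0, 0, 0))
  act <- array(0, sh)
  act[body] <- recipe$body_background * recipe$liver_conc
  act[liver] <- recipe$liver_conc
  act[tumour] <- recipe$uptake_ratio * recipe$liver_conc
  act[lungs] <- recipe$lung_shunt * recipe$liver_conc
  mu <- array(0, sh)
  mu[body] <- model$mu_soft
  mu[lungs] <- model$mu_lung
  list(true_activity = volume3d(act, spacing = sp, unit = "concentration"),
       masks = masks,
       mu_map = volume3d(mu, spacing = sp, unit = "mm^-1"))
}

# 1D linear resample of a (b x z) slice by a constant fractional offset
# along the first dimension, zero outside.
lerp_slice <- function(M, f) {
  j0 <- floor(f)
  w <- f - j0
  shift2 <- function(M, s) {
    out <- matrix(0, nrow(M), ncol(M))
    src <- seq_len(nrow(M)) + s
    ok <- src >= 1 & src <= nrow(M)
    out[ok, ] <- M[src[ok], ]
    out
  }
  (1 - w) * shift2(M, j0) + w * shift2(M, j0 + 1)
}

#' Apply depth-dependent attenuation
#'
#' Each voxel is attenuated by the mean over a fan of in-plane ray
#' directions of `exp(-integral of mu)` from the voxel to the volume edge
#' (mu is zero outside the body, so this equals the path to the body
#' surface). The line integral uses a half-voxel-trapezoid recurrence
#' marched slice by slice along the dominant axis of each direction, so the
#' axis-aligned uniform-mu case reproduces `exp(-mu * depth)` with depth
#' measured from the voxel centre to the surface.
#'
#' @param true_activity a [volume3d].
#' @param mu_map a [volume3d] of attenuation coefficients, mm^-1, on the
#'   same grid.
#' @param model a [degradation_model] (`n_projection_dirs`).
#' @param directions optional matrix of unit in-plane directions (n x 2),
#'   overriding the default fan.
#' @return a [volume3d]; nowhere larger than the input.
#' @export
apply_attenuation <- function(true_activity, mu_map,
                              model = degradation_model(),
                              directions = NULL) {
  stopifnot(is_volume3d(true_activity), is_volume3d(mu_map))
  stop_if_grid_mismatch(true_activity, mu_map, "activity and mu map")
  if (is.null(directions)) {
    ang <- (seq_len(model$n_projection_dirs) - 0.5) * pi / model$n_projection_dirs
    directions <- cbind(cos(ang), sin(ang))
  }
  d <- dim(true_activity$values)
  sp <- true_activity$spacing
  factor <- array(0, d)
  for (r in seq_len(nrow(directions))) {
    u <- directions[r, ]
    I <- ray_integral_inplane(mu_map$values, sp, u)
    factor <- factor + exp(-I)
  }
  out <- true_activity$values * factor / nrow(directions)
  volume3d(out, spacing = sp, origin = true_activity$origin,
           unit = true_activity$unit)
}

# Line integral of mu from each voxel centre to the grid edge along the
# in-plane direction u = (ux, uy), marched along the dominant axis.
ray_integral_inplane <- function(mu, sp, u) {
  d <- dim(mu)
  if (abs(u[1]) >= abs(u[2])) {
    a <- 1L; b <- 2L
  } else {
    a <- 2L; b <- 1L
  }
  da <- sign(u[a])
  if (da == 0) da <- 1
  fb <- u[b] / abs(u[a])                       # fractional step along b
  step_mm <- sqrt(sp[a]^2 + (fb * sp[b])^2)    # physical step length
  I <- array(0, d)
  n_a <- d[a]
  # iterate from exit slice inward
  order_idx <- if (da > 0) seq(n_a, 1) else seq(1, n_a)
  get_slice <- function(arr, ia) {
    if (a == 1L) arr[ia, , ] else aperm(arr[, ia, , drop = FALSE],
                                        c(1, 3, 2))[, , 1]
  }
  set_slice <- function(arr, ia, M) {
    if (a == 1L) arr[ia, , ] <- M else arr[, ia, ] <- M
    arr
  }
  prevI <- NULL
  prevMu <- NULL
  for (ia in order_idx) {
    mu_here <- get_slice(mu, ia)
    if (is.null(prevI)) {
      Islice <- 0.5 * step_mm * mu_here
    } else {
      mu_next <- lerp_slice(prevMu, fb)
      I_next <- lerp_slice(prevI, fb)
      Islice <- 0.5 * step_mm * (mu_here + mu_next) + I_next
    }
    I <- set_slice(I, ia, Islice)
    prevI <- Islice
    prevMu <- mu_here
  }
  I
}

#' Apply energy-window-trapped scatter
#'
#' A fraction `f` of counts is redistributed by a broad normalised 3D
#' Gaussian: `out = (1 - f) * primary + f * G(primary)`. The blurred
#' component is renormalised to the primary total, so the operation
#' conserves total counts exactly — scatter trapped in the photopeak window
#' redistributes counts, it does not remove them.
#'
#' @param primary a [volume3d] of counts.
#' @param model a [degradation_model] (`scatter_fraction`,
#'   `scatter_kernel_fwhm_mm`).
#' @return a [volume3d] with the same total.
#' @export
apply_scatter <- function(primary, model = degradation_model()) {
  stopifnot(is_volume3d(primary))
  f <- model$scatter_fraction
  if (f == 0) return(primary)
  sigma_vox <- model$scatter_kernel_fwhm_mm / (2 * sqrt(2 * log(2))) /
    primary$spacing
  g <- gaussian_blur3(primary$values, sigma_vox)
  tot <- sum(primary$values)
  gs <- sum(g)
  if (gs > 0) g <- g * (tot / gs)
  volume3d((1 - f) * primary$values + f * g, spacing = primary$spacing,
           origin = primary$origin, unit = primary$unit)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate paired NC / AC / ASC count and dose maps
#'
#' The three correction states of one acquisition: ASC is the true activity
#' scaled to the expected total counts; AC is scatter-degraded only; NC is
#' attenuation- then scatter-degraded (the system cannot scatter-correct
#' without attenuation-correcting, so no attenuation-only state exists).
#' Optional Poisson noise enters at the count level, before calibration.
#' Dose maps are derived per state through [dose_from_counts()] with the
#' shared injected activity, so the WL-total deposited energy is identical
#' across states and the states differ only in spatial distribution.
#'
#' @param recipe a [phantom_recipe].
#' @param model a [degradation_model].
#' @return list with `counts` and `doses` (each a named list NC/AC/ASC),
#'   `masks`, `true_activity`, `mu_map`.
#' @export
generate_task_triplet <- function(recipe, model = degradation_model()) {
  ph <- build_phantom(recipe, model)
  tot <- sum(ph$true_activity$values)
  scale <- recipe$total_counts / tot
  true_counts <- volume3d(ph$true_activity$values * scale,
                          spacing = ph$true_activity$spacing, unit = "counts")
  asc <- true_counts
  ac <- apply_scatter(true_counts, model)
  nc <- apply_scatter(apply_attenuation(true_counts, ph$mu_map, model), model)
  counts <- list(NC = nc, AC = ac, ASC = asc)
  if (model$poisson_noise) {
    counts <- with_seed(recipe$seed, {
      lapply(counts, function(cm) {
        volume3d(array(as.numeric(rpois(length(cm$values),
                                        pmax(cm$values, 0))),
                       dim(cm$values)),
                 spacing = cm$spacing, origin = cm$origin, unit = "counts")
      })
    })
  }
  wl <- region_mask(ph$masks, "wl")
  doses <- lapply(names(counts), function(st) {
    dose_from_counts(counts[[st]], wl, recipe$injected_activity_gbq,
                     correction_state = st)
  })
  names(doses) <- names(counts)
  list(counts = counts, doses = doses, masks = ph$masks,
       true_activity = ph$true_activity, mu_map = ph$mu_map)
}
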