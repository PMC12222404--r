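# Pluggable volumetric regressors behind a fit/predict contract. A regressor
# specification is a list with:
#   name        label
#   n_features  number of feature channels
#   features(values, spacing) -> list of 3D arrays (the channels)
#   init(config) -> initial parameter vector
#   trainable   logical
# Members are fitted with Adam on the L1 patch loss by fit_regressor() and
# applied voxelwise by predict_regressor(). The default member is a
# physics-informed voxelwise linear model; the architecture slot is where a
# full-scale attention network would plug in on GPU hardware.

#' Default volumetric regressor: physics-guided voxelwise linear model
#'
#' Predicts the reference dose at each voxel as a learned linear
#' combination of correction basis channels derived from the input dose
#' map alone:
#' \itemize{
#'   \item the raw value and a fine constant-preserving blur (local
#'     smoothing);
#'   \item a scatter-scale blur (the forward scatter operator at nominal
#'     kernel width);
#'   \item an inverse-attenuation channel `x / a(v)`, where `a(v)` is the
#'     mean over an in-plane fan of ray directions of the Beer-Lambert
#'     factor through the image support at a nominal soft-tissue
#'     attenuation coefficient;
#'   \item a scatter-deconvolved variant (fixed-point Neumann iteration of
#'     the nominal scatter model) divided by `a(v)`;
#'   \item the full nominal correction chain re-scattered (deconvolve,
#'     divide by `a`, re-apply scatter) — the physics prediction of the
#'     attenuation-corrected-only state.
#' }
#' The attenuation-dependent channels are rescaled per case to the input's
#' total over the high-uptake support, mirroring the patient-relative
#' calibration applied downstream. Which channels matter for a given task
#' — and how strongly — is learned from data; the member is initialised at
#' identity (weight one on the raw value), so an untrained member is a
#' no-op.
#'
#' @param fine_blur_sigma_vox standard deviation (voxels) of the fine blur
#'   channel.
#' @param scatter_fraction_nominal,scatter_fwhm_nominal_mm nominal scatter
#'   model used by the deconvolution channels.
#' @param mu_nominal_mm attenuation coefficient used for the ray factors,
#'   mm^-1.
#' @param n_dirs in-plane ray directions over 180 degrees.
#' @param neumann_iter scatter-deconvolution fixed-point iterations.
#' @return a regressor specification.
#' @export
regressor_voxfeat <- function(fine_blur_sigma_vox = 1.5,
                              scatter_fraction_nominal = 0.35,
                              scatter_fwhm_nominal_mm = 30,
                              mu_nominal_mm = 0.011,
                              n_dirs = 8L, neumann_iter = 3L) {
  f0 <- scatter_fraction_nominal
  list(
    name = "voxfeat",
    n_features = 6L,
    trainable = TRUE,
    features = function(values, spacing) {
      x <- values
      q <- as.numeric(quantile(x, 0.999, names = FALSE))
      if (q <= 0) {
        # degenerate (empty) input: all channels collapse to the raw value
        return(list(x, x, x, x, x, x))
      }
      support <- close6(x > 0.002 * q)  # body-scale support
      hot <- x > 0.01 * q               # high-uptake support (liver-scale)
      if (!any(hot)) hot <- support
      sig_sc <- scatter_fwhm_nominal_mm / (2 * sqrt(2 * log(2))) / spacing
      sblur <- function(z) {
        g <- gaussian_blur3(z, sig_sc)
        s <- sum(z); gs <- sum(g)
        if (gs > 0) g * (s / gs) else g
      }
      mu <- array(0, dim(x))
      mu[support] <- mu_nominal_mm
      ang <- (seq_len(n_dirs) - 0.5) * pi / n_dirs
      a <- array(0, dim(x))
      for (th in ang)
        a <- a + exp(-ray_integral_inplane(mu, spacing, c(cos(th), sin(th))))
      a <- a / n_dirs
      g_sc <- sblur(x)
      u <- x
      for (k in seq_len(neumann_iter)) u <- (x - f0 * sblur(u)) / (1 - f0)
      uia <- u / a
      za <- (1 - f0) * uia + f0 * sblur(uia)
      tot <- sum(x[hot])
      resc <- function(z) {
        s <- sum(z[hot])
        if (s > 0) z * (tot / s) else z
      }
      list(x, gaussian_blur3_norm(x, fine_blur_sigma_vox), g_sc,
           resc(x / a), resc(uia), resc(za))
    },
    init = function(config) c(1, 0, 0, 0, 0, 0)
  )
}

#' Identity regressor
#'
#' A fixed unit-weight regressor that returns its input patch unchanged.
#' Useful as a translation-invariant member for engine contract checks
#' (seam-freeness, ensemble linearity).
#'
#' @return a regressor specification.
#' @export
regressor_identity <- function() {
  list(
    name = "identity",
    n_features = 1L,
    trainable = FALSE,
    features = function(values, spacing) list(values),
    init = function(config) 1
  )
}

# Apply a (linear) member to a feature patch (list of 3D arrays).
predict_regressor <- function(regressor, model, feature_patch) {
  w <- model$weights
  out <- array(0, dim(feature_patch[[1]]))
  for (i in seq_along(w)) out <- out + w[i] * feature_patch[[i]]
  out
}

patch_loss_l1 <- function(w, samples) {
  tot <- 0
  for (s in samples) {
    pred <- 0
    for (i in seq_along(w)) pred <- pred + w[i] * s$features[[i]]
    tot <- tot + mean(abs(pred - s$reference))
  }
  tot / length(samples)
}

# Adam on the member parameters, minimising the L1 patch loss with decoupled
# L2 weight decay and optional feature dropout (each step drops channels
# with the configured probability, rescaling the kept ones).
fit_regressor <- function(regressor, train_cases, val_cases, config) {
  w <- regressor$init(config)
  if (!isTRUE(regressor$trainable)) {
    return(list(model = list(weights = w),
                history = list(train_loss = NA_real_, val_loss = NA_real_)))
  }
  nf <- length(w)
  m <- numeric(nf); v <- numeric(nf)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0L
  p <- config$patch_size
  train_loss <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    samples <- unlist(lapply(train_cases, function(cs)
      sample_feature_patches(cs$feats, cs$ref, p,
                             config$patches_per_volume, config$augment)),
      recursive = FALSE)
    samples <- samples[sample.int(length(samples))]
    nb <- ceiling(length(samples) / config$batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      batch <- samples[(((b - 1) * config$batch_size) + 1):
                         min(b * config$batch_size, length(samples))]
      keep <- if (config$dropout > 0) runif(nf) >= config$dropout else rep(TRUE, nf)
      if (!any(keep)) keep[sample.int(nf, 1)] <- TRUE
      scale <- 1 / mean(keep)
      grad <- numeric(nf)
      bl <- 0
      for (s in batch) {
        pred <- 0
        for (i in which(keep)) pred <- pred + scale * w[i] * s$features[[i]]
        r <- pred - s$reference
        bl <- bl + mean(abs(r))
        sg <- sign(r)
        for (i in which(keep)) grad[i] <- grad[i] + scale * mean(sg * s$features[[i]])
      }
      grad <- grad / length(batch)
      bl <- bl / length(batch)
      t <- t + 1L
      m <- b1 * m + (1 - b1) * grad
      v <- b2 * v + (1 - b2) * grad^2
      mh <- m / (1 - b1^t)
      vh <- v / (1 - b2^t)
      # decoupled weight decay (AdamW): the decay is not renormalised by v
      w <- w - config$learning_rate *
        (mh / (sqrt(vh) + eps) + config$weight_decay * w)
      ep_loss <- ep_loss + bl
    }
    train_loss[epoch] <- ep_loss / nb
  }
  val_loss <- NA_real_
  if (length(val_cases) > 0) {
    val_samples <- unlist(lapply(val_cases, function(cs)
      sample_feature_patches(cs$feats, cs$ref, p,
                             config$patches_per_volume, augment = FALSE)),
      recursive = FALSE)
    val_loss <- patch_loss_l1(w, val_samples)
  }
  list(model = list(weights = w),
       history = list(train_loss = train_loss, val_loss = val_loss))
}
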