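#' Voxel-level agreement metrics between dose maps
#'
#' Computes the standard battery over an evaluation mask: mean error
#' (ME, signed), mean absolute error (MAE), MSE, RMSE, peak signal-to-noise
#' ratio (PSNR, with the data range taken as the in-mask reference maximum),
#' relative error RE = 100 (sum(pred) - sum(ref)) / sum(ref), relative
#' absolute error RAE = 100 sum|pred - ref| / sum(ref), and SSIM over the
#' mask bounding box (7^3 uniform window, k1 = 0.01, k2 = 0.03 on the
#' in-box reference range). RE and RAE use the global sum-ratio form; the
#' per-voxel form diverges at near-zero reference voxels and is available
#' via `rel_form = "per_voxel"` with a 0.1 Gy reference floor.
#'
#' ME is antisymmetric in its arguments and MAE/MSE/RMSE symmetric; PSNR,
#' SSIM's range convention and RE/RAE are tied to the reference argument.
#'
#' @param pred,ref [dose_map]s (or [volume3d]s) on a shared grid.
#' @param mask logical evaluation mask (default: whole grid).
#' @param ssim_window odd window edge for SSIM (default 7).
#' @param rel_form "global" (sum ratio) or "per_voxel" (floored).
#' @return an object of class `voxel_metric_report`: list with `me`, `mae`,
#'   `mse`, `rmse`, `psnr_db`, `ssim`, `re_pct`, `rae_pct`, `n_voxels`, and
#'   the parameter record.
#' @export
voxel_report <- function(pred, ref, mask = NULL, ssim_window = 7L,
                         rel_form = c("global", "per_voxel")) {
  stopifnot(is_volume3d(pred), is_volume3d(ref))
  stop_if_grid_mismatch(pred, ref, "pred/ref")
  rel_form <- match.arg(rel_form)
  if (is.null(mask)) mask <- array(TRUE, dim(ref$values))
  if (!any(mask)) stop("voxel_report: empty evaluation mask", call. = FALSE)
  p <- pred$values[mask]
  r <- ref$values[mask]
  diff <- p - r
  me <- mean(diff)
  mae <- mean(abs(diff))
  mse <- mean(diff^2)
  rmse <- sqrt(mse)
  rng <- max(r)
  psnr <- if (mse == 0) Inf else 10 * log10(rng^2 / mse)
  sr <- sum(r)
  if (sr <= 0) stop("voxel_report: zero reference sum, relative metrics undefined",
                    call. = FALSE)
  if (rel_form == "global") {
    re <- 100 * (sum(p) - sr) / sr
    rae <- 100 * sum(abs(diff)) / sr
  } else {
    rf <- pmax(r, 0.1)
    re <- 100 * mean((p - r) / rf)
    rae <- 100 * mean(abs(p - r) / rf)
  }
  ss <- ssim3d(pred$values, ref$values, mask = mask, window = ssim_window)
  structure(list(me = me, mae = mae, mse = mse, rmse = rmse, psnr_db = psnr,
                 ssim = ss, re_pct = re, rae_pct = rae,
                 n_voxels = sum(mask),
                 params = list(ssim_window = ssim_window,
                               psnr_range = rng, rel_form = rel_form)),
            class = "voxel_metric_report")
}

#' @export
print.voxel_metric_report <- function(x, ...) {
  cat(sprintf("<voxel_metric_report> n = %d voxels\n", x$n_voxels))
  cat(sprintf("  ME %.4g Gy  MAE %.4g Gy  RMSE %.4g Gy  PSNR %.4g dB\n",
              x$me, x$mae, x$rmse, x$psnr_db))
  cat(sprintf("  SSIM %.6g (%.4g%%)  RE %.4g%%  RAE %.4g%%\n",
              x$ssim, 100 * x$ssim, x$re_pct, x$rae_pct))
  invisible(x)
}

mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  list(lo = apply(w, 2, min), hi = apply(w, 2, max))
}

#' Structural similarity between 3D volumes
#'
#' Mean SSIM over all full cubic windows of the mask bounding box, with a
#' uniform window and the conventional stabilisation constants
#' C1 = (k1 L)^2, C2 = (k2 L)^2 where L is the in-box range of the
#' reference. Identical inputs give exactly 1.
#'
#' @param a,b numeric 3D arrays (evaluated as a vs reference b).
#' @param mask optional logical array; SSIM is computed over its bounding
#'   box.
#' @param window odd window edge (default 7).
#' @param k1,k2 stabilisation constants.
#' @return scalar mean SSIM in [-1, 1].
#' @export
ssim3d <- function(a, b, mask = NULL, window = 7L, k1 = 0.01, k2 = 0.03) {
  stopifnot(identical(dim(a), dim(b)), window %% 2 == 1)
  if (!is.null(mask) && any(mask)) {
    bb <- mask_bbox(mask)
    a <- a[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
    b <- b[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
  }
  if (identical(a, b)) return(1)
  r <- (window - 1L) %/% 2L
  if (any(dim(a) < window))
    stop("ssim3d: volume smaller than the SSIM window", call. = FALSE)
  L <- diff(range(b))
  if (L == 0) L <- max(abs(b), 1e-12)
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  nw <- window^3
  sa <- box_sum_valid(a, r) / nw
  sb <- box_sum_valid(b, r) / nw
  saa <- box_sum_valid(a * a, r) / nw
  sbb <- box_sum_valid(b * b, r) / nw
  sab <- box_sum_valid(a * b, r) / nw
  # unbiased (n-1) sample variances/covariance, as is conventional
  ub <- nw / (nw - 1)
  va <- ub * (saa - sa^2)
  vb <- ub * (sbb - sb^2)
  cab <- ub * (sab - sa * sb)
  ssim_map <- ((2 * sa * sb + c1) * (2 * cab + c2)) /
    ((sa^2 + sb^2 + c1) * (va + vb + c2))
  mean(ssim_map)
}

#' Joint-histogram comparison with a least-squares fit
#'
#' Bins in-mask (reference, predicted) voxel pairs into a 2D histogram for
#' plotting and fits predicted on reference by ordinary least squares on
#' the raw voxel pairs (not the binned counts), reporting slope, intercept
#' and R^2.
#'
#' @param pred,ref [volume3d]s on a shared grid.
#' @param mask logical evaluation mask (default: whole grid).
#' @param n_bins histogram bins per axis (default 64).
#' @return object of class `joint_histogram_fit` with `slope`, `intercept`,
#'   `r_squared`, `counts` (n_bins x n_bins), `breaks_ref`, `breaks_pred`.
#' @export
joint_histogram_fit <- function(pred, ref, mask = NULL, n_bins = 64L) {
  stopifnot(is_volume3d(pred), is_volume3d(ref))
  stop_if_grid_mismatch(pred, ref, "pred/ref")
  if (is.null(mask)) mask <- array(TRUE, dim(ref$values))
  if (!any(mask)) stop("joint_histogram_fit: empty mask", call. = FALSE)
  p <- pred$values[mask]
  r <- ref$values[mask]
  if (stats::var(r) == 0)
    stop("joint_histogram_fit: constant reference, fit degenerate", call. = FALSE)
  # closed-form simple OLS (avoids summary.lm's perfect-fit warning on
  # identical maps)
  slope <- stats::cov(p, r) / stats::var(r)
  intercept <- mean(p) - slope * mean(r)
  r2 <- if (stats::var(p) == 0) 1 else stats::cor(p, r)^2
  br <- seq(min(r), max(r), length.out = n_bins + 1L)
  bp <- seq(min(p), max(p), length.out = n_bins + 1L)
  ir <- pmin(pmax(findInterval(r, br, rightmost.closed = TRUE), 1L), n_bins)
  ip <- pmin(pmax(findInterval(p, bp, rightmost.closed = TRUE), 1L), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  tab <- table(ir, ip)
  counts[cbind(as.integer(rownames(tab))[row(tab)],
               as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 counts = counts, breaks_ref = br, breaks_pred = bp),
            class = "joint_histogram_fit")
}

#' @export
print.joint_histogram_fit <- function(x, ...) {
  cat(sprintf("<joint_histogram_fit> slope %.4f  intercept %.4g  R^2 %.5f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Dose profile along a grid line
#'
#' Returns the dose values along the grid line parallel to `axis` passing
#' nearest to a world-coordinate point, with world-mm positions along the
#' axis.
#'
#' @param map a [volume3d].
#' @param axis "x", "y" or "z".
#' @param through_point world coordinates (mm), length 3.
#' @return data.frame with `position_mm` and `dose`.
#' @export
line_profile <- function(map, axis = c("x", "y", "z"),
                         through_point = NULL) {
  stopifnot(is_volume3d(map))
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  d <- dim(map$values)
  if (is.null(through_point))
    through_point <- map$origin + (d - 1) / 2 * map$spacing
  idx <- round((through_point - map$origin) / map$spacing)
  if (any(idx < 0) || any(idx > d - 1))
    stop("line_profile: point outside the volume", call. = FALSE)
  sel <- as.list(idx + 1)
  sel[[ax]] <- seq_len(d[ax])
  vals <- map$values[sel[[1]], sel[[2]], sel[[3]]]
  pos <- map$origin[ax] + (seq_len(d[ax]) - 1) * map$spacing[ax]
  data.frame(position_mm = pos, dose = as.numeric(vals))
}
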