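#' Gamma-index criteria
#'
#' A distance-to-agreement (DTA, mm) / dose-difference (DD, % of the
#' normalisation dose) pair. The default normalisation is global (the
#' reference maximum over the evaluated voxels), the dominant convention;
#' local normalisation (by each voxel's own reference dose) is available.
#' Voxels whose reference dose falls below `low_dose_threshold` percent of
#' the global normalisation dose are excluded (default 0: all evaluated).
#'
#' @param dta_mm distance-to-agreement, mm (> 0).
#' @param dd_pct dose difference, percent (> 0).
#' @param normalisation "global" or "local".
#' @param low_dose_threshold_pct exclusion threshold, percent of the global
#'   normalisation dose.
#' @return an object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dta_mm, dd_pct, normalisation = c("global", "local"),
                           low_dose_threshold_pct = 0) {
  if (dta_mm <= 0 || dd_pct <= 0)
    stop("gamma_criteria: DTA and DD must be > 0", call. = FALSE)
  structure(list(dta_mm = dta_mm, dd_pct = dd_pct,
                 normalisation = match.arg(normalisation),
                 low_dose_threshold_pct = low_dose_threshold_pct),
            class = "gamma_criteria")
}

#' The three standard criteria for Y-90 SIRT gamma evaluation
#'
#' 4.795 mm / 1% (one SPECT voxel, the most stringent), 10 mm / 5% (SPECT
#' spatial resolution) and 15 mm / 10% (accounting for the low quality of
#' bremsstrahlung SPECT).
#'
#' @return list of three [gamma_criteria].
#' @export
sirt_gamma_criteria <- function() {
  list(gamma_criteria(4.795, 1), gamma_criteria(10, 5), gamma_criteria(15, 10))
}

#' 3D gamma index between dose maps
#'
#' For each evaluated reference voxel, the minimum over nearby evaluated-map
#' positions of the combined spatial/dosimetric disagreement
#' \deqn{\gamma(r) = \min_e \sqrt{\|r-e\|^2/DTA^2 + (D_e(e)-D_r(r))^2/(DD \cdot D_{norm})^2}}
#' with the evaluated map sampled trilinearly on a 1/3-voxel refinement
#' grid within a search radius of `2 * DTA` (gamma values are capped at 2;
#' capped voxels count as failures, so pass rates are unaffected). A voxel
#' passes when gamma <= 1. The roles of the maps are not symmetric; the
#' reference map is always the comparison baseline.
#'
#' @param ref,eval_map [dose_map]s (or [volume3d]s) on a shared grid.
#' @param criteria a [gamma_criteria].
#' @param mask logical; which reference voxels to evaluate (default all).
#' @param refine sub-voxel refinement factor (default 3).
#' @param cap gamma search/cap bound (default 2).
#' @return object of class `gamma_result`: `gamma` (3D array, NaN where
#'   excluded), `pass_rate_pct`, `criteria`, `d_norm`.
#' @export
gamma_map <- function(ref, eval_map, criteria, mask = NULL, refine = 3L,
                      cap = 2) {
  stopifnot(is_volume3d(ref), is_volume3d(eval_map),
            inherits(criteria, "gamma_criteria"))
  stop_if_grid_mismatch(ref, eval_map, "ref/eval dose maps")
  d <- dim(ref$values)
  if (is.null(mask)) mask <- array(TRUE, d)
  dn_global <- max(ref$values[mask])
  if (dn_global <= 0)
    stop("gamma_map: reference is zero over the evaluation mask", call. = FALSE)
  evalmask <- mask
  if (criteria$low_dose_threshold_pct > 0) {
    evalmask <- evalmask &
      (ref$values >= criteria$low_dose_threshold_pct / 100 * dn_global)
  }
  if (!any(evalmask))
    stop("gamma_map: all voxels excluded from evaluation", call. = FALSE)
  dnorm_vec <- if (criteria$normalisation == "global") {
    rep(dn_global, length(ref$values))
  } else {
    as.numeric(ref$values)
  }
  g <- cpp_gamma(as.numeric(ref$values), as.numeric(eval_map$values),
                 as.integer(d), as.numeric(ref$spacing),
                 criteria$dta_mm, criteria$dd_pct / 100, dnorm_vec,
                 as.integer(refine), cap, as.logical(evalmask))
  garr <- array(g, d)
  evaluated <- !is.na(garr)
  pass <- 100 * sum(garr[evaluated] <= 1) / sum(evaluated)
  structure(list(gamma = garr, pass_rate_pct = pass, criteria = criteria,
                 d_norm = dn_global, refine = refine, cap = cap),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> DTA %.4g mm / DD %.4g%% (%s): pass rate %.2f%%\n",
              x$criteria$dta_mm, x$criteria$dd_pct,
              x$criteria$normalisation, x$pass_rate_pct))
  invisible(x)
}

#' Gamma pass-rate table per region and criteria
#'
#' Computes one gamma map per criteria entry over the body mask (the
#' whole-image row) and aggregates per-region pass rates for every named
#' mask in the segmentation set.
#'
#' @param ref,eval_map [dose_map]s on a shared grid.
#' @param masks a [segmentation_set]; its `body` mask defines the evaluated
#'   voxels and the `whole_image` row.
#' @param criteria_list list of [gamma_criteria] (default
#'   [sirt_gamma_criteria()]).
#' @param regions region names to report (default: all in `masks`).
#' @param ... passed to [gamma_map()].
#' @return data.frame with columns `region`, `dta_mm`, `dd_pct`,
#'   `pass_rate_pct`.
#' @export
gamma_pass_table <- function(ref, eval_map, masks,
                             criteria_list = sirt_gamma_criteria(),
                             regions = NULL, ...) {
  stopifnot(inherits(masks, "segmentation_set"))
  body <- masks$masks$body %||% array(TRUE, dim(ref$values))
  if (is.null(regions)) regions <- region_names(masks)
  rows <- list()
  for (cr in criteria_list) {
    gr <- gamma_map(ref, eval_map, cr, mask = body, ...)
    evaluated <- !is.na(gr$gamma)
    rate <- function(m) {
      mm <- m & evaluated
      if (!any(mm)) return(NA_real_)
      100 * sum(gr$gamma[mm] <= 1) / sum(mm)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(region = "whole_image", dta_mm = cr$dta_mm,
                 dd_pct = cr$dd_pct, pass_rate_pct = gr$pass_rate_pct)
    for (rn in regions) {
      rows[[length(rows) + 1L]] <-
        data.frame(region = rn, dta_mm = cr$dta_mm, dd_pct = cr$dd_pct,
                   pass_rate_pct = rate(region_mask(masks, rn)))
    }
  }
  do.call(rbind, rows)
}
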