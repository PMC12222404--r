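#' Uniform-phantom specification
#'
#' Describes the calibration acquisition: a uniform cylindrical phantom of
#' known volume filled with a known Y-90 activity, scanned for a known
#' duration, with a central region of interest (ROI) covering a stated
#' fraction of the phantom used for counting. Decay correction from assay to
#' scan is the caller's responsibility.
#'
#' @param volume_ml phantom volume in mL (default 6200).
#' @param activity_mbq activity at scan time in MBq (default 605.33).
#' @param duration_s acquisition duration in seconds.
#' @param roi_fraction fraction of the phantom volume used as the central
#'   ROI (default 0.7).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_ml = 6200, activity_mbq = 605.33,
                         duration_s, roi_fraction = 0.7) {
  stopifnot(volume_ml > 0, activity_mbq > 0, duration_s > 0,
            roi_fraction > 0, roi_fraction <= 1)
  structure(list(volume_ml = volume_ml, activity_mbq = activity_mbq,
                 duration_s = duration_s, roi_fraction = roi_fraction),
            class = "phantom_spec")
}

#' Scanner conversion factor from a uniform phantom
#'
#' Computes the count-rate sensitivity of the system from a uniform-phantom
#' acquisition. The central ROI is obtained by isotropically eroding the
#' phantom mask until its volume is at most `roi_fraction` of the full mask
#' (ties broken toward the smaller ROI). The factor is
#' \deqn{CF = \frac{\sum_{ROI} counts / t}{(A/V)\, V_{ROI}}}
#' i.e. count rate per MBq contained in the ROI, with the activity
#' concentration \eqn{A/V} taken from the phantom specification.
#'
#' The factor is reported for auditability; patient dosimetry uses the
#' patient-relative calibration (see [patient_count_to_activity_scale()]),
#' which is independent of scanner sensitivity and acquisition time.
#'
#' @param phantom_image a [volume3d] of counts.
#' @param spec a [phantom_spec].
#' @param phantom_mask logical 3D array delineating the phantom interior.
#' @return object of class `conversion_factor` with fields `value`
#'   (counts/s per MBq), `roi_voxels`, `roi_volume_ml`, `spec`.
#' @export
phantom_conversion_factor <- function(phantom_image, spec, phantom_mask) {
  stopifnot(is_volume3d(phantom_image), inherits(spec, "phantom_spec"))
  if (!identical(dim(phantom_mask), dim(phantom_image$values)))
    stop("phantom_conversion_factor: mask not on the image grid", call. = FALSE)
  full_n <- sum(phantom_mask)
  if (full_n == 0) stop("phantom_conversion_factor: empty phantom mask", call. = FALSE)
  roi <- phantom_mask
  while (sum(roi) > spec$roi_fraction * full_n) {
    eroded <- erode6(roi)
    if (!any(eroded)) break
    roi <- eroded
  }
  if (!any(roi))
    stop("phantom_conversion_factor: ROI empty after erosion", call. = FALSE)
  vox_ml <- voxel_volume(phantom_image) / 1000  # mm^3 -> mL
  roi_counts <- sum(phantom_image$values[roi])
  roi_volume_ml <- sum(roi) * vox_ml
  conc <- spec$activity_mbq / spec$volume_ml            # MBq/mL
  cf <- (roi_counts / spec$duration_s) / (conc * roi_volume_ml)
  structure(list(value = cf, unit = "counts/s per MBq",
                 roi_voxels = sum(roi), roi_volume_ml = roi_volume_ml,
                 spec = spec, date = format(Sys.Date())),
            class = "conversion_factor")
}

#' @export
print.conversion_factor <- function(x, ...) {
  cat(sprintf("<conversion_factor> %.6g %s (ROI %d voxels, %.1f mL)\n",
              x$value, x$unit, x$roi_voxels, x$roi_volume_ml))
  invisible(x)
}

#' Patient-relative count-to-activity calibration
#'
#' Scales the SPECT count map so that the total activity in the whole liver
#' (WL) equals the net injected activity:
#' \deqn{scale = A_{inj} \cdot 1000 / \sum_{WL} counts \quad [MBq/count]}
#' Per-voxel activity is then `scale * counts(v)`. The calibration is
#' invariant to any global rescaling of the count map, so it is independent
#' of scanner sensitivity and acquisition time and avoids any geometry
#' mismatch between calibration source and patient anatomy.
#'
#' @param spect_counts a [volume3d] of counts.
#' @param wl_mask logical 3D array, the whole-liver mask.
#' @param injected_activity_gbq net injected Y-90 activity, GBq.
#' @return list with `scale_mbq_per_count` and `activity` (a [volume3d] of
#'   per-voxel activity in MBq, image-wide).
#' @export
patient_count_to_activity_scale <- function(spect_counts, wl_mask,
                                            injected_activity_gbq) {
  stopifnot(is_volume3d(spect_counts))
  if (!identical(dim(wl_mask), dim(spect_counts$values)))
    stop("patient_count_to_activity_scale: WL mask not on the image grid",
         call. = FALSE)
  if (!is.numeric(injected_activity_gbq) || injected_activity_gbq <= 0)
    stop("patient_count_to_activity_scale: injected activity must be > 0",
         call. = FALSE)
  wl_counts <- sum(spect_counts$values[wl_mask])
  if (wl_counts <= 0)
    stop("patient_count_to_activity_scale: zero counts in WL", call. = FALSE)
  scale <- injected_activity_gbq * 1000 / wl_counts
  activity <- volume3d(spect_counts$values * scale,
                       spacing = spect_counts$spacing,
                       origin = spect_counts$origin, unit = "MBq")
  list(scale_mbq_per_count = scale, activity = activity)
}
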