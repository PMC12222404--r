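#' Y-90 physical constants for local energy deposition dosimetry
#'
#' @param half_life_h physical half-life in hours (default 64.1).
#' @param mean_energy_mev mean emitted beta energy per decay in MeV
#'   (default 0.93; nuclear-data compilations also quote 0.937).
#' @param tissue_density_g_cm3 tissue density in g/cm^3 (default 1.05,
#'   liver); applied uniformly unless a density map is supplied.
#' @return an object of class `radionuclide_params`.
#' @export
radionuclide_params <- function(half_life_h = 64.1, mean_energy_mev = 0.93,
                                tissue_density_g_cm3 = 1.05) {
  if (half_life_h <= 0 || mean_energy_mev <= 0 || tissue_density_g_cm3 <= 0)
    stop("radionuclide_params: all parameters must be > 0", call. = FALSE)
  structure(list(half_life_h = half_life_h,
                 mean_energy_mev = mean_energy_mev,
                 tissue_density_g_cm3 = tissue_density_g_cm3),
            class = "radionuclide_params")
}

MEV_TO_J <- 1.602176634e-13

#' Mark a volume as a dose map
#'
#' Attaches the correction state (NC / AC / ASC) that is propagated through
#' training-task contracts and every evaluation.
#'
#' @param image a non-negative [volume3d] in Gy.
#' @param correction_state one of "NC", "AC", "ASC".
#' @param provenance optional free-form provenance string.
#' @return object of class `c("dose_map", "volume3d")`.
#' @export
dose_map <- function(image, correction_state = c("NC", "AC", "ASC"),
                     provenance = NULL) {
  stopifnot(is_volume3d(image))
  correction_state <- match.arg(correction_state)
  if (min(image$values) < 0)
    stop("dose_map: dose values must be non-negative", call. = FALSE)
  image$unit <- "Gy"
  image$correction_state <- correction_state
  image$provenance <- provenance
  class(image) <- c("dose_map", "volume3d")
  image
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> state %s\n", x$correction_state))
  NextMethod()
}

correction_state <- function(x) {
  if (!inherits(x, "dose_map")) stop("expected a dose_map", call. = FALSE)
  x$correction_state
}

#' Absorbed dose by the local energy deposition method
#'
#' LDM assumes microspheres are permanently trapped (no biological
#' clearance) and deposit all beta energy in the voxel of decay (no
#' crossfire). The absorbed dose in a voxel holding activity A (MBq) is
#' \deqn{D = A \cdot \frac{T_{1/2}}{\ln 2} \cdot \bar{E} / m}
#' with the half-life in seconds, the mean energy converted MeV to J, and
#' the voxel mass m from the tissue density and voxel volume.
#'
#' @param activity_map a [volume3d] of per-voxel activity in MBq.
#' @param params a [radionuclide_params].
#' @param correction_state correction state recorded on the output.
#' @return a [dose_map] in Gy.
#' @export
ldm_dose <- function(activity_map, params = radionuclide_params(),
                     correction_state = "ASC") {
  stopifnot(is_volume3d(activity_map), inherits(params, "radionuclide_params"))
  if (min(activity_map$values) < 0)
    stop("ldm_dose: activity must be non-negative", call. = FALSE)
  tau_s <- params$half_life_h * 3600 / log(2)       # time-integration factor
  e_j <- params$mean_energy_mev * MEV_TO_J          # J per decay
  mass_kg <- params$tissue_density_g_cm3 * voxel_volume(activity_map) * 1e-6
  dose <- activity_map$values * 1e6 * tau_s * e_j / mass_kg
  dose_map(volume3d(dose, spacing = activity_map$spacing,
                    origin = activity_map$origin, unit = "Gy"),
           correction_state = correction_state,
           provenance = "ldm_dose")
}

#' Dose map from SPECT counts via patient-relative calibration
#'
#' Composition of [patient_count_to_activity_scale()] and [ldm_dose()]: the
#' count map is scaled so total WL activity equals the net injected
#' activity, then converted voxelwise to absorbed dose. The scale derived
#' from the WL is applied image-wide, so organs outside the liver (lungs,
#' kidneys, stomach) receive dose from the same map. Total energy deposited
#' in the WL is therefore fixed by the injected activity regardless of the
#' spatial count distribution.
#'
#' @param spect_counts a [volume3d] of counts.
#' @param wl_mask logical whole-liver mask.
#' @param injected_activity_gbq net injected activity, GBq.
#' @param params a [radionuclide_params].
#' @param correction_state correction state recorded on the output.
#' @return a [dose_map] in Gy.
#' @export
dose_from_counts <- function(spect_counts, wl_mask, injected_activity_gbq,
                             params = radionuclide_params(),
                             correction_state = "ASC") {
  cal <- patient_count_to_activity_scale(spect_counts, wl_mask,
                                         injected_activity_gbq)
  ldm_dose(cal$activity, params, correction_state = correction_state)
}

#' Total energy deposited in a region
#'
#' \eqn{\sum_v D(v) m(v)} in joules; under patient-relative calibration the
#' WL total equals \eqn{A_{inj} \cdot 1.443\,T_{1/2} \cdot \bar{E}}.
#'
#' @param dose a [dose_map].
#' @param mask logical region mask.
#' @param params a [radionuclide_params] (for the voxel mass).
#' @return energy in J.
#' @export
deposited_energy_j <- function(dose, mask, params = radionuclide_params()) {
  stopifnot(is_volume3d(dose))
  mass_kg <- params$tissue_density_g_cm3 * voxel_volume(dose) * 1e-6
  sum(dose$values[mask]) * mass_kg
}
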