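#' Voxel calibration for a 3D-SIM acquisition
#'
#' Bundles the physical calibration of an image stack: lateral pixel size,
#' axial step between z-sections, and the effective axial and lateral
#' resolution (full width at half maximum) of the imaging system. The axial
#' sampling default is 125 nm (z-sections 0.125 um apart) and the axial
#' resolution default 360 nm, the midpoint of the 340-380 nm range typical
#' of linear 3D-SIM; both are wavelength-dependent in practice and can be
#' overridden per dataset. The lateral resolution default of 120 nm is a
#' typical reconstructed linear-SIM value.
#'
#' @param pixel_xy lateral pixel size, nm per pixel (> 0).
#' @param z_step axial distance between consecutive z-sections, nm (> 0).
#' @param axial_fwhm axial resolution FWHM, nm (> 0).
#' @param lateral_fwhm lateral resolution FWHM, nm (> 0).
#' @return An object of class `voxel_calibration`.
#' @export
#' @examples
#' voxel_calibration(pixel_xy = 40)
voxel_calibration <- function(pixel_xy = 40, z_step = 125,
                              axial_fwhm = 360, lateral_fwhm = 120) {
  vals <- c(pixel_xy = pixel_xy, z_step = z_step,
            axial_fwhm = axial_fwhm, lateral_fwhm = lateral_fwhm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all calibration lengths must be finite and strictly positive")
  }
  structure(as.list(vals), class = "voxel_calibration")
}

#' @export
print.voxel_calibration <- function(x, ...) {
  cat(sprintf(
    "voxel_calibration: %.1f nm/px (xy), %.1f nm z-step, FWHM %.0f nm axial / %.0f nm lateral\n",
    x$pixel_xy, x$z_step, x$axial_fwhm, x$lateral_fwhm))
  invisible(x)
}

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
FWHM_SIGMA <- 2 * sqrt(2 * log(2))

fwhm_to_sigma <- function(fwhm) fwhm / FWHM_SIGMA
sigma_to_fwhm <- function(sigma) sigma * FWHM_SIGMA

#' Run configuration for the analysis pipelines
#'
#' Collects every tunable of the measurement pipelines in one place so a
#' run is fully described by (config, seed, inputs). Defaults follow the
#' measurement conventions of the underlying assays: peaks brighter than
#' 30% of a profile's maximum are fitted, and centriole masks are dilated
#' by 3 pixels radially before intensity quantification.
#'
#' @param calibration a [voxel_calibration()].
#' @param peak_threshold_fraction fraction of the profile maximum above
#'   which samples belong to a peak region (0 < f < 1; default 0.30).
#' @param dilation_radius_px radial dilation of segmented focus masks in
#'   pixels (non-negative integer; default 3).
#' @param fit_pad samples added on each side of a peak region before
#'   Gaussian fitting in [profile_pipeline()] (default 2); keeps the
#'   4-parameter fit well-posed when the axial sampling step is coarse
#'   relative to the peak width.
#' @param window_px side of the square local-mean window of the adaptive
#'   threshold, pixels (odd; default 51).
#' @param offset_fraction adaptive-threshold offset as a fraction of the
#'   local dynamic range (default 0).
#' @param min_area_px,max_area_px area filter for segmented foci, pixels.
#' @param min_cilium_length_um minimum Feret extent for a marker-channel
#'   object to be called a cilium, micrometres (default 1).
#' @param random_seed integer seed recorded with every pipeline run.
#' @param ring_convention `"outer-edge"` (default) measures rings at the
#'   outer half-maximum edge; `"peak"` at the radial intensity maximum.
#' @return An object of class `run_config`.
#' @export
run_config <- function(calibration = voxel_calibration(),
                       peak_threshold_fraction = 0.30,
                       dilation_radius_px = 3L,
                       fit_pad = 2L,
                       window_px = 51L,
                       offset_fraction = 0,
                       min_area_px = 4L,
                       max_area_px = 400L,
                       min_cilium_length_um = 1,
                       random_seed = 1L,
                       ring_convention = c("outer-edge", "peak")) {
  stopifnot(inherits(calibration, "voxel_calibration"))
  if (!(peak_threshold_fraction > 0 && peak_threshold_fraction < 1)) {
    stop("peak_threshold_fraction must lie strictly between 0 and 1")
  }
  if (dilation_radius_px < 0 || dilation_radius_px != round(dilation_radius_px)) {
    stop("dilation_radius_px must be a non-negative integer")
  }
  structure(list(
    calibration = calibration,
    peak_threshold_fraction = peak_threshold_fraction,
    dilation_radius_px = as.integer(dilation_radius_px),
    fit_pad = as.integer(fit_pad),
    window_px = as.integer(window_px),
    offset_fraction = offset_fraction,
    min_area_px = as.integer(min_area_px),
    max_area_px = as.integer(max_area_px),
    min_cilium_length_um = min_cilium_length_um,
    random_seed = as.integer(random_seed),
    ring_convention = match.arg(ring_convention)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; calibration fields live in
#' a nested `calibration:` section. Missing keys fall back to defaults.
#'
#' @param path path to a YAML config file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cal_args <- raw$calibration %||% list()
  cal <- do.call(voxel_calibration, cal_args)
  args <- raw[setdiff(names(raw), "calibration")]
  do.call(run_config, c(list(calibration = cal), args))
}

#' Write a run configuration to a YAML file
#' @param config a `run_config`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$calibration <- unclass(config$calibration)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one structured log line per pipeline stage
log_stage <- function(stage, seed = NA, ..., t0 = NULL) {
  extras <- list(...)
  kv <- if (length(extras)) {
    paste(sprintf("%s=%s", names(extras), vapply(extras, format, "")),
          collapse = " ")
  } else ""
  elapsed <- if (!is.null(t0)) {
    sprintf(" elapsed=%.2fs", as.numeric(proc.time()["elapsed"]) - t0)
  } else ""
  message(sprintf("[centriolr %s] stage=%s seed=%s %s%s",
                  as.character(utils::packageVersion("centriolr")),
                  stage, format(seed), kv, elapsed))
}
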