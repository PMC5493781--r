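#' Ground truth for axially separated protein bands
#'
#' Describes, per imaging channel, one or more protein bands along the
#' centriole (z) axis: band centres in nm (axial origin at the middle of
#' the simulated stack), the intrinsic band thickness, and per-band peak
#' amplitudes. At render time each band is broadened by the axial
#' resolution, giving an effective FWHM of
#' `sqrt(band_fwhm^2 + axial_fwhm^2)` — the quantity a Gaussian fit to the
#' axial profile actually sees.
#'
#' @param centers named list, one numeric vector of band centres (nm) per
#'   channel; at least one band per channel.
#' @param band_fwhm intrinsic axial band thickness (FWHM), nm.
#' @param amplitudes optional named list matching `centers` with per-band
#'   peak amplitudes (counts above background); default 3000 for every
#'   band, a bright SIM-like signal.
#' @return An object of class `band_truth`.
#' @export
band_truth <- function(centers, band_fwhm = 80, amplitudes = NULL) {
  stopifnot(is.list(centers), length(centers) >= 1, !is.null(names(centers)))
  if (any(vapply(centers, length, 0L) < 1)) {
    stop("at least one band per channel")
  }
  if (any(!is.finite(unlist(centers)))) stop("band centers must be finite")
  if (band_fwhm <= 0) stop("band_fwhm must be > 0")
  if (is.null(amplitudes)) {
    amplitudes <- lapply(centers, function(x) rep(3000, length(x)))
  }
  stopifnot(identical(lengths(amplitudes), lengths(centers)))
  structure(list(centers = centers, band_fwhm = band_fwhm,
                 amplitudes = amplitudes), class = "band_truth")
}

#' Closed-form noiseless axial profile of a band truth
#'
#' Sum of Gaussians at the true band centres with effective FWHM
#' `sqrt(band_fwhm^2 + axial_fwhm^2)`; the value the renderer places at
#' the spot centre of each z-section (before background/offset/noise).
#'
#' @param truth a [band_truth()].
#' @param channel channel label.
#' @param z axial positions, nm.
#' @param axial_fwhm axial resolution FWHM, nm.
#' @return Numeric vector of signal amplitudes at `z`.
#' @export
axial_band_profile <- function(truth, channel, z, axial_fwhm = 360) {
  s_eff <- fwhm_to_sigma(sqrt(truth$band_fwhm^2 + axial_fwhm^2))
  cts <- truth$centers[[channel]]
  amp <- truth$amplitudes[[channel]]
  out <- numeric(length(z))
  for (k in seq_along(cts)) {
    out <- out + amp[k] * exp(-(z - cts[k])^2 / (2 * s_eff^2))
  }
  out
}

#' Render a synthetic multi-channel z-stack of axial protein bands
#'
#' Each channel receives a lateral Gaussian spot (FWHM =
#' `calibration$lateral_fwhm`) at the image centre of every z-section,
#' with per-section amplitude following [axial_band_profile()] sampled at
#' the stack's z positions (`z_step` apart, axial origin mid-stack).
#' Background, dark offset and camera noise are then applied per voxel.
#'
#' @param truth a [band_truth()].
#' @param calibration a [voxel_calibration()].
#' @param noise a [noise_model()].
#' @param seed integer seed for the noise draw.
#' @param nz number of z-sections (default 25).
#' @param size_px lateral image side, pixels.
#' @return A list with elements `stack` (an [image_stack()]) and `truth`
#'   (augmented with `z_positions`, the section centres in nm, and
#'   `spot_px`, the 0-based pixel coordinates of the lateral spot).
#' @export
generate_axial_bands <- function(truth, calibration = voxel_calibration(),
                                 noise = noise_model(), seed = 1,
                                 nz = 25, size_px = 21) {
  z <- (seq_len(nz) - (nz + 1) / 2) * calibration$z_step
  rng <- range(unlist(truth$centers))
  if (rng[1] < min(z) || rng[2] > max(z)) {
    stop(sprintf("band centers [%.0f, %.0f] nm outside the simulated axial extent [%.0f, %.0f] nm",
                 rng[1], rng[2], min(z), max(z)))
  }
  s_lat <- fwhm_to_sigma(calibration$lateral_fwhm)
  px <- calibration$pixel_xy
  c0 <- (size_px - 1) / 2 * px
  xs <- (seq_len(size_px) - 1) * px
  spot <- exp(-outer((xs - c0)^2, (xs - c0)^2, "+") / (2 * s_lat^2))

  set.seed(derive_seed(seed, 0))
  chans <- lapply(stats::setNames(nm = names(truth$centers)), function(ch) {
    amp_z <- axial_band_profile(truth, ch, z, calibration$axial_fwhm)
    vol <- array(0, dim = c(size_px, size_px, nz))
    for (i in seq_len(nz)) {
      vol[, , i] <- apply_noise(amp_z[i] * spot, noise)
    }
    vol
  })
  truth$z_positions <- z
  truth$spot_px <- rep((size_px - 1) / 2, 2)
  stk <- image_stack(chans, calibration, dark_offset = noise$dark_offset)
  list(stack = stk, truth = truth)
}
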