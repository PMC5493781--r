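#' Ground truth for a synthetic cell population
#'
#' Bernoulli state model of the per-cell phenotypes scored in
#' serum-starvation ciliogenesis assays: whether the cell ciliates,
#' whether CP110 persists at both centrioles (two foci) or only one, and
#' whether a ciliary membrane marker (RAB8A/SMO surrogate) is present
#' given a cilium. States are drawn independently per cell; all
#' randomness derives from `seed` through a per-scene counter so any
#' scene can be re-rendered in isolation.
#'
#' @param n_cells number of cells (>= 1).
#' @param p_ciliated probability a cell grows a cilium.
#' @param p_two_cp110_foci probability of CP110 foci at both centrioles;
#'   otherwise a single focus is rendered.
#' @param p_marker_positive_given_cilium probability the marker channel
#'   is positive for a ciliated cell.
#' @param seed integer master seed.
#' @return An object of class `population_truth`.
#' @export
population_truth <- function(n_cells = 300, p_ciliated = 0.8,
                             p_two_cp110_foci = 0.2,
                             p_marker_positive_given_cilium = 0.7,
                             seed = 1L) {
  probs <- c(p_ciliated, p_two_cp110_foci, p_marker_positive_given_cilium)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_cells < 1) stop("n_cells must be >= 1")
  structure(list(n_cells = as.integer(n_cells), p_ciliated = p_ciliated,
                 p_two_cp110_foci = p_two_cp110_foci,
                 p_marker_positive_given_cilium = p_marker_positive_given_cilium,
                 seed = as.integer(seed)),
            class = "population_truth")
}

# default calibration of the widefield-like phenotype scenes: 110 nm/px,
# deconvolved-widefield lateral resolution
scene_calibration <- function() {
  voxel_calibration(pixel_xy = 110, z_step = 1500,
                    axial_fwhm = 600, lateral_fwhm = 280)
}

# Gaussian spot, amplitude at the (0-based, px) centre
render_spot <- function(size_px, center, amplitude, sigma_px) {
  xs <- seq_len(size_px) - 1
  amplitude * exp(-outer((xs - center[2])^2, (xs - center[1])^2, "+") /
                    (2 * sigma_px^2))
}

# Segment from a to b (0-based px) with Gaussian cross-section
render_segment <- function(size_px, a, b, amplitude, sigma_px) {
  xs <- seq_len(size_px) - 1
  X <- matrix(xs, size_px, size_px, byrow = TRUE)
  Y <- matrix(xs, size_px, size_px)
  v <- b - a
  len2 <- sum(v^2)
  t <- pmin(pmax(((X - a[1]) * v[1] + (Y - a[2]) * v[2]) / len2, 0), 1)
  d2 <- (X - (a[1] + t * v[1]))^2 + (Y - (a[2] + t * v[2]))^2
  amplitude * exp(-d2 / (2 * sigma_px^2))
}

#' Render a synthetic cell population with per-cell ground truth
#'
#' Each scene is a projected multi-channel image of one cell's centrosome
#' neighbourhood: a `centriole` channel with the mother/daughter focus
#' pair (660 nm apart, random orientation, jittered placement); a
#' `cp110` channel with foci at both centrioles or at one, per the drawn
#' state; a `cilia` channel where ciliated cells carry a 2-5 um
#' line-segment surrogate cilium anchored at the mother centriole; and a
#' `marker` channel (RAB8A/SMO surrogate) decorating the proximal
#' micrometre of the cilium for marker-positive cells. Camera noise
#' follows the [noise_model()]. Default amplitudes (centriole 10000,
#' cp110 8000, cilium 3000, marker 5000 counts) emulate bright 16-bit
#' immunofluorescence against a 200-count background.
#'
#' @param truth a [population_truth()].
#' @param noise a [noise_model()].
#' @param calibration a [voxel_calibration()]; default widefield-like
#'   110 nm/px scenes.
#' @param size_px scene side, pixels (default 96).
#' @return A list: `scenes` (list of [image_stack()]), `labels` (data
#'   frame with `cell_id`, `ciliated`, `n_cp110_foci`, `marker_positive`
#'   — `NA` for non-ciliated cells — plus rendered geometry), and the
#'   input `truth`.
#' @export
generate_cell_population <- function(truth, noise = noise_model(),
                                     calibration = scene_calibration(),
                                     size_px = 96) {
  px <- calibration$pixel_xy
  s_psf <- fwhm_to_sigma(calibration$lateral_fwhm) / px
  sep_px <- 660 / px
  scenes <- vector("list", truth$n_cells)
  labels <- vector("list", truth$n_cells)
  for (i in seq_len(truth$n_cells)) {
    set.seed(derive_seed(truth$seed, i))
    ciliated <- stats::runif(1) < truth$p_ciliated
    two_foci <- stats::runif(1) < truth$p_two_cp110_foci
    marker_pos <- if (ciliated) {
      stats::runif(1) < truth$p_marker_positive_given_cilium
    } else NA
    c0 <- (size_px - 1) / 2 + stats::runif(2, -5, 5)
    phi <- stats::runif(1, 0, 2 * pi)
    mother <- c0 + sep_px / 2 * c(cos(phi), sin(phi))
    daughter <- c0 - sep_px / 2 * c(cos(phi), sin(phi))

    centriole <- render_spot(size_px, mother, 10000, s_psf) +
      render_spot(size_px, daughter, 10000, s_psf)
    cp110 <- if (two_foci) {
      render_spot(size_px, mother, 8000, s_psf) +
        render_spot(size_px, daughter, 8000, s_psf)
    } else {
      render_spot(size_px, daughter, 8000, s_psf)
    }
    cilia <- matrix(0, size_px, size_px)
    marker <- matrix(0, size_px, size_px)
    cil_len_um <- NA_real_
    if (ciliated) {
      cil_len_um <- stats::runif(1, 2, 5)
      theta <- stats::runif(1, 0, 2 * pi)
      tip <- mother + cil_len_um * 1000 / px * c(cos(theta), sin(theta))
      tip <- pmin(pmax(tip, 1), size_px - 2)
      cilia <- render_segment(size_px, mother, tip, 3000, s_psf)
      if (isTRUE(marker_pos)) {
        frac <- min(1, 1000 / (cil_len_um * 1000))
        base_end <- mother + frac * (tip - mother)
        marker <- render_segment(size_px, mother, base_end, 5000, s_psf)
      }
    }
    chans <- list(centriole = centriole, cp110 = cp110,
                  cilia = cilia, marker = marker)
    noisy <- lapply(chans, apply_noise, noise = noise)
    scenes[[i]] <- image_stack(noisy, calibration,
                               dark_offset = noise$dark_offset)
    labels[[i]] <- data.frame(
      cell_id = i, ciliated = ciliated,
      n_cp110_foci = if (two_foci) 2L else 1L,
      marker_positive = marker_pos,
      cilium_length_um = cil_len_um,
      mother_x_px = mother[1], mother_y_px = mother[2],
      daughter_x_px = daughter[1], daughter_y_px = daughter[2])
  }
  list(scenes = scenes, labels = do.call(rbind, labels), truth = truth)
}
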