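#' Camera noise model for synthetic renders
#'
#' The simulators use a simple sCMOS-like model: photon-dependent shot
#' noise, additive Gaussian read noise and a constant dark offset,
#'
#'   observed = Poisson(signal + background) + dark_offset + N(0, gaussian_sd),
#'
#' clamped at zero. `background` is diffuse cellular/optical background
#' (it carries shot noise like any light); `dark_offset` is camera signal
#' with no light and carries only the Gaussian term. The expectation of a
#' noisy render equals the noiseless render
#' (signal + background + dark_offset), which is what makes the
#' dark-noise-subtraction step of the quantification pipeline exact in
#' expectation.
#'
#' @param background diffuse background, counts (>= 0).
#' @param dark_offset camera dark offset, counts (>= 0).
#' @param gaussian_sd read-noise standard deviation, counts (>= 0).
#' @param poisson logical; apply shot noise?
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(background = 200, dark_offset = 100,
                        gaussian_sd = 30, poisson = TRUE) {
  vals <- c(background, dark_offset, gaussian_sd)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("noise model parameters must be finite and non-negative")
  }
  structure(list(background = background, dark_offset = dark_offset,
                 gaussian_sd = gaussian_sd, poisson = isTRUE(poisson)),
            class = "noise_model")
}

#' Noise-free noise model (renders equal the noiseless image)
#' @export
#' @rdname noise_model
no_noise <- function(background = 0, dark_offset = 0) {
  noise_model(background = background, dark_offset = dark_offset,
              gaussian_sd = 0, poisson = FALSE)
}

#' Peak signal-to-noise ratio under a noise model
#'
#' SNR is defined as peak signal amplitude over the noise standard
#' deviation at the peak: `A / sqrt(A + background + gaussian_sd^2)` with
#' shot noise, `A / gaussian_sd` without.
#'
#' @param amplitude peak signal amplitude above background, counts.
#' @param noise a [noise_model()].
#' @return The peak SNR.
#' @export
snr_at <- function(amplitude, noise) {
  v <- noise$gaussian_sd^2 + if (noise$poisson) amplitude + noise$background else 0
  if (v == 0) return(Inf)
  amplitude / sqrt(v)
}

#' Choose read noise to hit a target peak SNR
#'
#' Keeps `amplitude`, `background` and shot noise fixed and solves for the
#' Gaussian read-noise s.d. that yields the requested peak SNR. Errors if
#' shot noise alone already exceeds the target noise level.
#'
#' @param amplitude peak signal amplitude above background, counts.
#' @param snr target peak signal-to-noise ratio.
#' @param background,dark_offset,poisson as in [noise_model()].
#' @return A [noise_model()] achieving the target SNR at `amplitude`.
#' @export
noise_for_snr <- function(amplitude, snr, background = 200,
                          dark_offset = 100, poisson = TRUE) {
  target_var <- (amplitude / snr)^2
  shot_var <- if (poisson) amplitude + background else 0
  if (target_var < shot_var) {
    stop(sprintf(
      "shot noise alone gives SNR %.1f < requested %.1f at amplitude %g; raise the amplitude",
      amplitude / sqrt(shot_var), snr, amplitude))
  }
  noise_model(background = background, dark_offset = dark_offset,
              gaussian_sd = sqrt(target_var - shot_var), poisson = poisson)
}

# Apply the camera model to a noiseless *signal* image (no background/offset
# included yet). Returns signal + background + dark_offset with noise, >= 0.
apply_noise <- function(signal, noise) {
  photons <- signal + noise$background
  if (noise$poisson) {
    photons <- stats::rpois(length(photons), lambda = photons)
  }
  out <- photons + noise$dark_offset
  if (noise$gaussian_sd > 0) {
    out <- out + stats::rnorm(length(out), sd = noise$gaussian_sd)
  }
  out <- pmax(out, 0)
  dim(out) <- dim(signal)
  out
}

# Deterministic per-item seed derivation from one user seed (Lehmer step),
# kept below 2^31 so set.seed() always accepts it.
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m)
  as.integer((s * 48271 + as.numeric(index) * 9973 + 1) %% m)
}
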