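#' Line specification for profile sampling
#'
#' A straight sampling line over a 2-D image, in 0-based pixel
#' coordinates (a pixel's physical position is its centre). Intensities
#' are averaged over `averaging_width` parallel samples perpendicular to
#' the line, mimicking a wide line-profile tool.
#'
#' @param start,end numeric `(x, y)` endpoints, 0-based pixel coordinates.
#' @param sampling_step distance between consecutive samples, nm.
#' @param averaging_width number of perpendicular samples averaged
#'   (odd integer >= 1).
#' @return An object of class `line_spec`.
#' @export
line_spec <- function(start, end, sampling_step, averaging_width = 1L) {
  stopifnot(length(start) == 2, length(end) == 2)
  if (all(start == end)) stop("line start and end must differ")
  if (sampling_step <= 0) stop("sampling_step must be > 0")
  if (averaging_width < 1 || averaging_width %% 2 == 0) {
    stop("averaging_width must be an odd integer >= 1")
  }
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 sampling_step = sampling_step,
                 averaging_width = as.integer(averaging_width)),
            class = "line_spec")
}

#' Ordered intensity profile along a line
#'
#' @param positions strictly increasing positions, nm.
#' @param intensities non-negative intensities, one per position.
#' @param channel channel label.
#' @return An object of class `line_profile`.
#' @export
line_profile <- function(positions, intensities, channel = "ch") {
  stopifnot(length(positions) == length(intensities))
  if (length(positions) < 5) stop("a line profile needs at least 5 samples")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and >= 0")
  }
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 channel = channel),
            class = "line_profile")
}

# Bilinear interpolation at 0-based pixel coordinates (x, y); vectorised.
bilinear_interp <- function(image, x, y) {
  ny <- nrow(image); nx <- ncol(image)
  x <- pmin(pmax(x, 0), nx - 1)
  y <- pmin(pmax(y, 0), ny - 1)
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  image[i00] * (1 - fx) * (1 - fy) + image[i01] * fx * (1 - fy) +
    image[i10] * (1 - fx) * fy + image[i11] * fx * fy
}

#' Sample an intensity profile along a line
#'
#' Samples bilinear-interpolated intensities at `sampling_step` nm
#' intervals from the line start, averaging over `averaging_width`
#' perpendicular offsets (1 px apart). Positions are distances from the
#' line start in nm.
#'
#' @param image 2-D intensity matrix (rows = y, columns = x).
#' @param line a [line_spec()]; endpoints must lie inside the image.
#' @param calibration a [voxel_calibration()].
#' @param scale_nm_per_px physical length of one pixel step along the
#'   line, nm (default `calibration$pixel_xy`); override when the image
#'   axis carries a different calibration, e.g. the z-per-tile scale of a
#'   section montage.
#' @param channel channel label attached to the profile.
#' @return A [line_profile()].
#' @export
sample_profile <- function(image, line, calibration = voxel_calibration(),
                           scale_nm_per_px = calibration$pixel_xy,
                           channel = "ch") {
  ny <- nrow(image); nx <- ncol(image)
  for (p in list(line$start, line$end)) {
    if (p[1] < 0 || p[1] > nx - 1 || p[2] < 0 || p[2] > ny - 1) {
      stop("line endpoints must lie inside the image")
    }
  }
  d <- line$end - line$start
  len_px <- sqrt(sum(d^2))
  u <- d / len_px                       # unit direction, px
  v <- c(-u[2], u[1])                   # unit perpendicular, px
  len_nm <- len_px * scale_nm_per_px
  n <- floor(len_nm / line$sampling_step) + 1
  t_nm <- (seq_len(n) - 1) * line$sampling_step
  t_px <- t_nm / scale_nm_per_px
  offs <- seq_len(line$averaging_width) - (line$averaging_width + 1) / 2
  acc <- numeric(n)
  for (o in offs) {
    xs <- line$start[1] + t_px * u[1] + o * v[1]
    ys <- line$start[2] + t_px * u[2] + o * v[2]
    acc <- acc + bilinear_interp(image, xs, ys)
  }
  line_profile(t_nm, acc / length(offs), channel)
}

#' Normalise a profile to unit maximum
#'
#' Divides intensities by their maximum so the output peaks at exactly 1;
#' sample ratios (profile shape) are unchanged. Idempotent.
#'
#' @param profile a [line_profile()].
#' @return A [line_profile()] with maximum intensity 1.
#' @export
normalize_max <- function(profile) {
  m <- max(profile$intensities)
  if (m <= 0) stop("cannot normalize an all-zero profile")
  profile$intensities <- profile$intensities / m
  profile
}

#' Find peak regions above a fraction of the profile maximum
#'
#' Returns the maximal contiguous runs of samples whose intensity is at
#' least `threshold_fraction` of the profile's maximum and that contain a
#' local maximum of the profile. These are the regions bright enough to be
#' fitted (default: brighter than 30% of the maximum). Runs are disjoint
#' and ordered by position; the global argmax always falls in some run.
#'
#' @param profile a [line_profile()].
#' @param threshold_fraction fraction of the maximum (0 < f < 1).
#' @return A list of integer vectors `c(first, last)` (1-based sample
#'   indices).
#' @export
find_peak_regions <- function(profile, threshold_fraction = 0.30) {
  y <- profile$intensities
  thr <- threshold_fraction * max(y)
  qual <- y >= thr
  runs <- rle(qual)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  n <- length(y)
  is_locmax <- vapply(seq_len(n), function(i) {
    left_ok <- i == 1 || y[i] >= y[i - 1]
    right_ok <- i == n || y[i] >= y[i + 1]
    left_ok && right_ok
  }, logical(1))
  out <- list()
  for (k in which(runs$values)) {
    idx <- starts[k]:ends[k]
    if (any(is_locmax[idx])) out[[length(out) + 1]] <- c(starts[k], ends[k])
  }
  out
}

#' Fit a one-dimensional Gaussian to a peak region
#'
#' Least-squares fit of `A * exp(-(x - mu)^2 / (2 sigma^2)) + C` over the
#' given sample range, by Levenberg–Marquardt. Initialisation is
#' deterministic: `mu` at the region argmax, `sigma` from the region width
#' (/ 2.355), `A` from the region's dynamic range, `C` at the region
#' minimum. `mu` is constrained to the region's position span and `sigma`
#' to be positive. Convergence: relative RSS tolerance 1e-8, at most 500
#' iterations.
#'
#' @param profile a [line_profile()].
#' @param region integer `c(first, last)` sample range (>= 4 samples).
#' @return An object of class `gaussian_peak_fit` with fields `mu`,
#'   `sigma`, `amplitude`, `offset` (all in profile units), `rss` and
#'   `n_samples`.
#' @export
fit_gaussian <- function(profile, region = c(1L, length(profile$positions))) {
  idx <- region[1]:region[2]
  if (length(idx) < 4) stop("peak region must hold at least 4 samples")
  x <- profile$positions[idx]
  y <- profile$intensities[idx]
  span <- range(x)
  # sigma from the intensity-weighted second moment of the region: a
  # width-of-region start makes the amplitude and offset terms collinear
  # on coarsely sampled peaks and the gradient singular
  mu0 <- x[which.max(y)]
  w <- y - min(y)
  s0 <- if (sum(w) > 0) sqrt(sum(w * (x - mu0)^2) / sum(w)) else diff(span) / 4
  s0 <- min(max(s0, diff(x)[1] / 2), diff(span))
  start <- c(mu = mu0, s = s0, A = max(y) - min(y), C = min(y))
  if (start["A"] <= 0) stop("flat region: no peak to fit")
  residual <- function(p) {
    y - (p[3] * exp(-(x - p[1])^2 / (2 * p[2]^2)) + p[4])
  }
  jacobian <- function(p) {
    e <- exp(-(x - p[1])^2 / (2 * p[2]^2))
    -cbind(p[3] * e * (x - p[1]) / p[2]^2,
           p[3] * e * (x - p[1])^2 / p[2]^3,
           e,
           rep(1, length(x)))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = residual, jac = jacobian,
      lower = c(span[1], diff(x)[1] / 10, 0, 0),
      upper = c(span[2], 10 * diff(span), Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-8)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 5)) {
    stop(sprintf(
      "Gaussian fit did not converge (%s); initialization was mu=%.3g sigma=%.3g A=%.3g C=%.3g",
      if (is.null(fit)) "optimizer error" else fit$message,
      start["mu"], start["s"], start["A"], start["C"]))
  }
  p <- fit$par
  structure(list(mu = unname(p[1]), sigma = unname(p[2]),
                 amplitude = unname(p[3]), offset = unname(p[4]),
                 rss = fit$deviance, n_samples = length(idx)),
            class = "gaussian_peak_fit")
}

#' Axial distance between two fitted peaks
#'
#' The unsigned difference between the Gaussian peak centres of two fits
#' made along the same line, in nm.
#'
#' @param fit_a,fit_b [fit_gaussian()] results.
#' @return `|mu_a - mu_b|` in nm.
#' @export
axial_distance <- function(fit_a, fit_b) abs(fit_a$mu - fit_b$mu)

# Fit the brightest peak of one channel of a montaged stack along an
# axial line at perpendicular offset `row_offset` (px).
fit_axial_channel <- function(stack, channel, config, row_offset = 0,
                              averaging_width = 5L) {
  ch <- get_channel(stack, channel)
  d <- dim(ch)
  tile_w <- d[2]
  mont <- montage_sections(stack, channel)
  cal <- stack$calibration
  cx <- (d[2] - 1) / 2
  cy <- (d[1] - 1) / 2 + row_offset
  ln <- line_spec(start = c(cx, cy), end = c(cx + (d[3] - 1) * tile_w, cy),
                  sampling_step = cal$z_step,
                  averaging_width = averaging_width)
  prof <- sample_profile(mont, ln, cal,
                         scale_nm_per_px = cal$z_step / tile_w,
                         channel = channel)
  prof <- normalize_max(prof)
  regions <- find_peak_regions(prof, config$peak_threshold_fraction)
  amax <- which.max(prof$intensities)
  reg <- NULL
  for (r in regions) if (amax >= r[1] && amax <= r[2]) reg <- r
  if (is.null(reg)) stop("no peak region contains the profile maximum")
  reg <- c(max(1L, reg[1] - config$fit_pad),
           min(length(prof$positions), reg[2] + config$fit_pad))
  fit_gaussian(prof, reg)
}

#' Axial-distance pipeline over a montaged z-stack
#'
#' For each channel: tile the z-sections into a montage, sample an axial
#' line profile through the lateral structure (one sample per section, at
#' the z-per-tile scale), normalise to the maximum, keep regions brighter
#' than the configured fraction of the maximum, and fit a 1-D Gaussian to
#' the region containing the global maximum (expanded by `config$fit_pad`
#' samples per side). Reports the unsigned peak-to-peak distance for each
#' requested channel pair, per line, plus the median and 25%/75% quantiles
#' across repeated lines.
#'
#' @param stack an [image_stack()] (e.g. from [generate_axial_bands()]).
#' @param channel_pairs list of `c(channel_a, channel_b)`; default: all
#'   unordered channel pairs.
#' @param config a [run_config()].
#' @param line_offsets perpendicular offsets (px, possibly fractional) of
#'   the repeated lines; default `0` (a single line).
#' @param averaging_width perpendicular samples averaged per line.
#' @return A list with `distances` (data frame: line, pair, channels,
#'   mu_a, mu_b, distance_nm) and `summary` (data frame: pair, n, median,
#'   q25, q75 of distance_nm).
#' @export
profile_pipeline <- function(stack, channel_pairs = NULL,
                             config = run_config(), line_offsets = 0L,
                             averaging_width = 5L) {
  chans <- names(stack$channels)
  if (length(chans) < 2) stop("need at least 2 channels for distances")
  if (is.null(channel_pairs)) {
    channel_pairs <- utils::combn(chans, 2, simplify = FALSE)
  }
  rows <- list()
  for (li in seq_along(line_offsets)) {
    fits <- lapply(stats::setNames(nm = chans), function(ch) {
      tryCatch(fit_axial_channel(stack, ch, config, line_offsets[li],
                                 averaging_width),
               error = function(e) {
                 stop(sprintf("channel '%s', line offset %g: %s", ch,
                              line_offsets[li], conditionMessage(e)))
               })
    })
    for (pr in channel_pairs) {
      rows[[length(rows) + 1]] <- data.frame(
        line = li, pair = paste(pr[1], pr[2], sep = "-"),
        channel_a = pr[1], channel_b = pr[2],
        mu_a = fits[[pr[1]]]$mu, mu_b = fits[[pr[2]]]$mu,
        distance_nm = axial_distance(fits[[pr[1]]], fits[[pr[2]]]))
    }
  }
  dist_df <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(dist_df, dist_df$pair), function(d) {
    q <- stats::quantile(d$distance_nm, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(pair = d$pair[1], n = nrow(d),
               median_nm = q[2], q25_nm = q[1], q75_nm = q[3])
  }))
  rownames(summ) <- NULL
  list(distances = dist_df, summary = summ)
}
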