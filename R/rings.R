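#' Boundary points of a toroidal ring
#'
#' A set of (x, y) positions in nm lying on the visible boundary of a
#' protein ring, either extracted automatically ([extract_boundary_points()])
#' or selected manually and loaded from CSV
#' ([boundary_points_from_csv()]).
#'
#' @param points numeric matrix with columns `x`, `y` in nm; at least 3
#'   non-collinear points.
#' @param source `"automated"` or `"manual-file"`.
#' @return An object of class `boundary_point_set`.
#' @export
boundary_point_set <- function(points, source = c("automated", "manual-file")) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  if (nrow(points) < 3) stop("need at least 3 boundary points")
  ctr <- scale(points, scale = FALSE)
  sv <- svd(ctr)$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) stop("boundary points are collinear")
  colnames(points) <- c("x", "y")
  structure(list(points = points, source = match.arg(source)),
            class = "boundary_point_set")
}

#' Manually selected boundary points from a CSV table
#'
#' Reads a table with columns `image_id`, `channel`, `x_px`, `y_px`
#' (0-based pixel coordinates) and converts the rows matching `image_id`
#' and `channel` to nm using the calibration.
#'
#' @param path CSV file path.
#' @param image_id,channel row filter.
#' @param calibration a [voxel_calibration()].
#' @return A [boundary_point_set()] with source `"manual-file"`.
#' @export
boundary_points_from_csv <- function(path, image_id, channel,
                                     calibration = voxel_calibration()) {
  df <- utils::read.csv(path)
  need <- c("image_id", "channel", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    stop("boundary CSV must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[df$image_id == image_id & df$channel == channel, ]
  if (nrow(df) < 3) stop("fewer than 3 boundary points for this image/channel")
  boundary_point_set(cbind(df$x_px, df$y_px) * calibration$pixel_xy,
                     source = "manual-file")
}

#' Extract ring boundary points by radial edge detection
#'
#' A reproducible, automated counterpart to interactive boundary-pixel
#' selection. From `center_guess`, `n_rays` equally spaced radial
#' intensity profiles are sampled (bilinear interpolation, 0.25 px
#' radial step) and baseline-corrected (default baseline: median of the
#' 2-px image border, a robust background + dark-offset estimate that is
#' not inflated by the ring itself). Because a circular ridge is
#' rotationally invariant about its centre, each ray's profile is first
#' averaged with its `arc_average` angular neighbours (a circular moving
#' average across rays), which suppresses camera noise without
#' distorting the radial shape. The boundary point of a ray is then
#' placed where its profile falls, outward of the radial maximum, to
#' half of that maximum -- the outer half-maximum edge -- with sub-pixel
#' linear interpolation between the two straddling samples. With
#' `convention = "peak"` the point is instead placed at the radial
#' intensity maximum (parabolic sub-sample refinement). Rays with no
#' qualifying edge are dropped; fewer than 3 surviving points is an
#' error.
#'
#' For rings whose diameter approaches the blurred ring width
#' (roughly twice `sqrt(ring_fwhm^2 + lateral_fwhm^2)`) the ring is not
#' resolved as an annulus and the outer-edge estimate carries a
#' noise-dependent bias of a few percent; see the methods vignette.
#'
#' @param image 2-D intensity matrix (e.g. a [max_z_project()]).
#' @param center_guess `(x, y)` 0-based pixel coordinates inside the
#'   ring; any interior point works since rays are cast to the contour.
#' @param calibration a [voxel_calibration()].
#' @param n_rays number of radial directions (default 36).
#' @param convention `"outer-edge"` (default) or `"peak"`.
#' @param baseline optional baseline intensity override, counts.
#' @param arc_average odd number of adjacent ray profiles averaged
#'   before edge detection (default 5; 1 disables).
#' @return A [boundary_point_set()] in nm.
#' @export
extract_boundary_points <- function(image, center_guess,
                                    calibration = voxel_calibration(),
                                    n_rays = 36,
                                    convention = c("outer-edge", "peak"),
                                    baseline = NULL, arc_average = 5) {
  convention <- match.arg(convention)
  ny <- nrow(image); nx <- ncol(image)
  cx <- center_guess[1]; cy <- center_guess[2]
  if (cx < 0 || cx > nx - 1 || cy < 0 || cy > ny - 1) {
    stop("center_guess must lie inside the image")
  }
  if (is.null(baseline)) {
    # median of the 2-px image border: signal-free by the generator's
    # field-margin precondition, and unbiased by the ring itself (the
    # full-image median rises with the ring's area fraction)
    border <- c(image[c(1, 2, ny - 1, ny), ],
                image[3:(ny - 2), c(1, 2, nx - 1, nx)])
    baseline <- stats::median(border)
  }
  step <- 0.25
  angles <- (seq_len(n_rays) - 1) * 2 * pi / n_rays
  # common radial grid: truncated at the largest radius that stays
  # inside the image for every direction, so rays share sample counts
  rmax <- min(cx, nx - 1 - cx, cy, ny - 1 - cy)
  if (rmax < 2 * step) stop("center_guess too close to the image border")
  r <- seq(0, rmax, by = step)
  profs <- vapply(angles, function(th) {
    bilinear_interp(image, cx + r * cos(th), cy + r * sin(th)) - baseline
  }, numeric(length(r)))
  if (arc_average > 1) {
    k <- (arc_average - 1) / 2
    profs <- vapply(seq_len(n_rays), function(i) {
      rowMeans(profs[, ((i - 1 + (-k:k)) %% n_rays) + 1, drop = FALSE])
    }, numeric(length(r)))
  }
  tol <- 1e-9 * max(abs(image))
  pts <- list()
  for (i in seq_len(n_rays)) {
    prof <- profs[, i]
    m <- which.max(prof)
    if (prof[m] <= tol) next
    if (convention == "outer-edge") {
      half <- prof[m] / 2
      after <- seq(m, length(r))
      k_rel <- which(prof[after] < half)
      if (!length(k_rel)) next
      k <- after[k_rel[1]]
      r_b <- r[k - 1] + (prof[k - 1] - half) * step / (prof[k - 1] - prof[k])
    } else {
      if (m == 1 || m == length(r)) next
      denom <- prof[m - 1] - 2 * prof[m] + prof[m + 1]
      delta <- if (denom < 0) 0.5 * (prof[m - 1] - prof[m + 1]) / denom else 0
      r_b <- r[m] + delta * step
    }
    th <- angles[i]
    pts[[length(pts) + 1]] <- c(cx + r_b * cos(th), cy + r_b * sin(th))
  }
  if (length(pts) < 3) {
    stop(sprintf("only %d of %d rays produced a boundary point; no usable ring edge",
                 length(pts), n_rays))
  }
  boundary_point_set(do.call(rbind, pts) * calibration$pixel_xy,
                     source = "automated")
}

#' Least-squares circle fit to boundary points
#'
#' Two-stage fit: the algebraic (Kasa) circle minimising
#' `sum((x^2 + y^2 + D x + E y + F)^2)` by linear least squares, refined
#' by geometric least squares minimising the sum of squared radial
#' residuals `sum((|p - c| - r)^2)` with damped Gauss-Newton steps
#' (relative tolerance 1e-10, at most 200 iterations; falls back to the
#' algebraic solution with a warning on non-convergence). The geometric
#' stage never increases the radial residual of the algebraic solution.
#'
#' @param points a [boundary_point_set()] (nm), or a 2-column matrix.
#' @return An object of class `ring_measurement`: `center` (x, y nm),
#'   `radius` and `diameter` (nm; `diameter = 2 * radius` exactly),
#'   `rms_residual` (nm) and `n_points`.
#' @export
fit_circle <- function(points) {
  if (!inherits(points, "boundary_point_set")) {
    points <- boundary_point_set(points)
  }
  p <- points$points
  x <- p[, 1]; y <- p[, 2]
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  coefs <- qr.solve(A, b)
  cx <- -coefs[1] / 2; cy <- -coefs[2] / 2
  r2 <- cx^2 + cy^2 - coefs[3]
  if (r2 <= 0) stop("degenerate geometry: algebraic fit has no real radius")
  r <- sqrt(r2)

  sse <- function(par) {
    d <- sqrt((x - par[1])^2 + (y - par[2])^2)
    sum((d - par[3])^2)
  }
  par <- c(cx, cy, r)
  cur <- sse(par)
  lambda <- 0
  converged <- FALSE
  for (it in seq_len(200)) {
    d <- sqrt((x - par[1])^2 + (y - par[2])^2)
    d[d == 0] <- 1e-12
    e <- d - par[3]
    J <- cbind(-(x - par[1]) / d, -(y - par[2]) / d, -1)
    JtJ <- crossprod(J)
    step <- tryCatch(
      solve(JtJ + lambda * diag(diag(JtJ)), -crossprod(J, e)),
      error = function(e) NULL)
    if (is.null(step)) break
    new_par <- par + as.numeric(step)
    new_sse <- if (new_par[3] > 0) sse(new_par) else Inf
    if (new_sse <= cur) {
      improved <- (cur - new_sse) <= 1e-10 * max(cur, 1e-300)
      par <- new_par
      cur <- new_sse
      lambda <- lambda / 10
      if (improved) { converged <- TRUE; break }
    } else {
      lambda <- max(lambda * 10, 1e-8)
      if (lambda > 1e8) break
    }
  }
  if (!converged && cur > sse(c(cx, cy, r))) {
    warning("geometric refinement did not converge; using algebraic fit")
    par <- c(cx, cy, r)
    cur <- sse(par)
  }
  structure(list(center = c(x = unname(par[1]), y = unname(par[2])),
                 radius = unname(par[3]),
                 diameter = 2 * unname(par[3]),
                 rms_residual = sqrt(cur / nrow(p)),
                 n_points = nrow(p),
                 source = points$source),
            class = "ring_measurement")
}

#' @export
print.ring_measurement <- function(x, ...) {
  cat(sprintf("ring_measurement: diameter %.1f nm (radius %.1f nm), center (%.1f, %.1f) nm, rms %.2f nm over %d points [%s]\n",
              x$diameter, x$radius, x$center[1], x$center[2],
              x$rms_residual, x$n_points, x$source))
  invisible(x)
}

#' Measure a ring diameter from an image stack
#'
#' The full diameter pipeline: maximum z-projection of the requested
#' channel, radial boundary-point extraction and geometric circle fit,
#' reporting the diameter in nm. Boundary points lying more than 2.5
#' radial r.m.s. residuals off the fitted circle (rays that latched onto
#' a noise crossing) are trimmed and the circle refitted, at most twice.
#' If `center_guess` is omitted it is taken as the intensity centroid of
#' the brightest decile of the projection.
#'
#' @param stack an [image_stack()].
#' @param channel channel label.
#' @param center_guess optional `(x, y)` 0-based pixel coordinates.
#' @param config a [run_config()]; `ring_convention` selects the
#'   outer-edge or peak-radius boundary definition.
#' @param n_rays number of radial directions.
#' @return A `ring_measurement` (see [fit_circle()]).
#' @export
measure_ring <- function(stack, channel, center_guess = NULL,
                         config = run_config(), n_rays = 36) {
  proj <- max_z_project(stack, channel)
  if (is.null(center_guess)) {
    thr <- stats::quantile(proj, 0.9)
    idx <- which(proj >= thr, arr.ind = TRUE)
    w <- proj[idx]
    center_guess <- c(sum((idx[, 2] - 1) * w), sum((idx[, 1] - 1) * w)) / sum(w)
  }
  pts <- extract_boundary_points(proj, center_guess, stack$calibration,
                                 n_rays = n_rays,
                                 convention = config$ring_convention)
  m <- fit_circle(pts)
  # up to two trimming passes: rays that latched onto a noise crossing
  # sit far off the circle and skew the geometric fit inward
  for (pass in 1:2) {
    p <- pts$points
    res <- abs(sqrt((p[, 1] - m$center[1])^2 + (p[, 2] - m$center[2])^2) -
                 m$radius)
    keep <- res <= 2.5 * max(m$rms_residual, 1e-9)
    if (all(keep) || sum(keep) < max(6, nrow(p) / 2)) break
    pts <- boundary_point_set(p[keep, , drop = FALSE], pts$source)
    m <- fit_circle(pts)
  }
  m
}
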