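# shift a matrix by (dy, dx), filling vacated cells with `fill`
shift_matrix <- function(m, dy, dx, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  ok_y <- ys >= 1 & ys <= ny; ok_x <- xs >= 1 & xs <= nx
  out[which(ok_y), which(ok_x)] <- m[ys[ok_y], xs[ok_x]]
  out
}

# 8-connected component labelling by iterative minimum-label propagation
label_components <- function(bw) {
  lab <- matrix(0, nrow(bw), ncol(bw))
  fg <- which(bw)
  lab[fg] <- seq_along(fg)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    prev <- lab
    for (o in offs) {
      sh <- shift_matrix(lab, o[1], o[2], fill = 0)
      take <- bw & sh > 0 & (lab == 0 | sh < lab)
      lab[take] <- sh[take]
    }
    if (identical(lab, prev)) break
  }
  ids <- sort(unique(lab[lab > 0]))
  lab[] <- match(lab, ids, nomatch = 0)
  lab
}

# exact local mean over a w x w box with replicate edge padding, via an
# integral image (no FFT: the comparison `pixel > local mean` must be
# exact on constant inputs)
box_mean <- function(m, w) {
  k <- w %/% 2
  ny <- nrow(m); nx <- ncol(m)
  P <- m[c(rep(1, k), seq_len(ny), rep(ny, k)),
         c(rep(1, k), seq_len(nx), rep(nx, k))]
  I <- matrix(0, nrow(P) + 1, ncol(P) + 1)
  I[-1, -1] <- apply(P, 2, cumsum)
  I[-1, ] <- t(apply(I[-1, ], 1, cumsum))
  ii <- seq_len(ny); jj <- seq_len(nx)
  (I[ii + w, jj + w, drop = FALSE] - I[ii, jj + w, drop = FALSE] -
      I[ii + w, jj, drop = FALSE] + I[ii, jj, drop = FALSE]) / w^2
}

#' Segment centriole/centrosome foci by adaptive thresholding
#'
#' Thresholds the reference (centriole-marker) image at the local mean
#' over a square window plus `offset_fraction` of the image's dynamic
#' range (max minus min), labels the resulting foreground with
#' 8-connected components, discards components outside the
#' `[min_area, max_area]` pixel range, and orders the surviving labels by
#' descending integrated reference intensity. With `offset_fraction = 0`
#' the threshold is the plain local mean, appropriate for deconvolved or
#' noise-free inputs; on noisy raw images a positive offset suppresses
#' background speckle in windows that contain no signal.
#'
#' @param reference_image 2-D matrix of the centriole marker channel
#'   (typically a z-projection).
#' @param window_px side of the square local window, pixels (odd).
#' @param offset_fraction threshold offset as a fraction of the image
#'   dynamic range (default 0).
#' @param min_area,max_area component area filter, pixels.
#' @return An integer label matrix (0 = background); zero surviving
#'   components gives an all-zero mask with a warning.
#' @export
segment_foci <- function(reference_image, window_px = 51L,
                         offset_fraction = 0, min_area = 4L,
                         max_area = 400L) {
  w <- as.integer(window_px)
  if (w %% 2 == 0) w <- w + 1L
  w <- min(w, 2L * min(dim(reference_image)) - 1L)
  thr <- box_mean(reference_image, w)
  if (offset_fraction != 0) {
    thr <- thr + offset_fraction * diff(range(reference_image))
  }
  # relative tolerance guards against floating-point residue of the
  # integral-image means in signal-free regions
  bw <- reference_image > thr + 1e-9 * diff(range(reference_image))
  lab <- label_components(bw)
  if (max(lab) == 0) {
    warning("no foci found by adaptive thresholding")
    return(lab)
  }
  keep <- integer(0)
  sums <- numeric(0)
  for (id in seq_len(max(lab))) {
    px <- lab == id
    a <- sum(px)
    if (a >= min_area && a <= max_area) {
      keep <- c(keep, id)
      sums <- c(sums, sum(reference_image[px]))
    }
  }
  if (!length(keep)) {
    warning("no foci within the area filter")
    return(matrix(0L, nrow(lab), ncol(lab)))
  }
  keep <- keep[order(sums, decreasing = TRUE)]
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

#' Radially dilate a label mask
#'
#' Grows every label by a Euclidean disc of radius `radius_px` (a pixel
#' joins the grown label if its centre lies within `radius_px` of an
#' original label pixel, i.e. `dx^2 + dy^2 <= r^2`). Where discs of
#' different labels overlap, the pixel goes to the nearest original
#' label, ties to the lower label id. Original pixels keep their label.
#'
#' @param mask integer label matrix (0 = background).
#' @param radius_px dilation radius, pixels (non-negative integer).
#' @return The dilated label matrix.
#' @export
dilate_labels <- function(mask, radius_px = 3L) {
  r <- as.integer(radius_px)
  if (r < 0) stop("radius_px must be a non-negative integer")
  if (r == 0 || max(mask) == 0) return(mask)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs$d2 <- offs$dy^2 + offs$dx^2
  offs <- offs[offs$d2 <= r^2 & offs$d2 > 0, ]
  offs <- offs[order(offs$d2), ]
  out <- mask
  dist2 <- matrix(Inf, nrow(mask), ncol(mask))
  dist2[mask > 0] <- 0
  for (i in seq_len(nrow(offs))) {
    src <- shift_matrix(mask, offs$dy[i], offs$dx[i], fill = 0)
    d2 <- offs$d2[i]
    cand <- src > 0 & mask == 0 &
      (d2 < dist2 | (d2 == dist2 & src < out))
    out[cand] <- src[cand]
    dist2[cand] <- d2
  }
  out
}

#' Per-focus dark-subtracted intensity quantification
#'
#' For every label of a (typically dilated) focus mask and every channel
#' of the stack, computes the mean and integrated intensity of
#' `max(0, pixel - dark_offset)` over the label's pixels. Channels with
#' more than one z-section are maximum-projected first, matching
#' quantification on z-projected images. `integrated = mean * area` holds
#' exactly.
#'
#' @param mask integer label matrix matching the stack's x/y dimensions.
#' @param stack an [image_stack()]; its `dark_offset` is subtracted.
#' @return A data frame with one row per focus: `focus_id`, `area_px`,
#'   then `mean_<channel>` and `integrated_<channel>` per channel. Empty
#'   mask gives a zero-row frame.
#' @export
quantify <- function(mask, stack) {
  d_im <- dim(stack$channels[[1]])
  if (!all(dim(mask) == d_im[1:2])) {
    stop("mask and stack x/y dimensions differ")
  }
  chans <- names(stack$channels)
  projs <- lapply(chans, function(ch) {
    pr <- max_z_project(stack, ch)
    pmax(pr - stack$dark_offset, 0)
  })
  names(projs) <- chans
  n_lab <- max(mask)
  cols <- c("focus_id", "area_px",
            paste0("mean_", chans), paste0("integrated_", chans))
  if (n_lab == 0) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    return(out)
  }
  rows <- lapply(seq_len(n_lab), function(id) {
    px <- mask == id
    a <- sum(px)
    means <- vapply(projs, function(p) mean(p[px]), numeric(1))
    row <- c(id, a, means, means * a)
    stats::setNames(as.list(row), cols)
  })
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Population summary with 2-s.d. band and 95% confidence interval
#'
#' Mean, sample standard deviation (n - 1 denominator), the mean +/- 2
#' s.d. band describing the population spread, and the Student-t 95%
#' confidence interval of the mean.
#'
#' @param values numeric vector of per-cell (or per-focus) measurements.
#' @param n_min minimum sample size (default 5).
#' @return An object of class `population_stats` with fields `n`, `mean`,
#'   `sd`, `band_2sd` and `ci95`.
#' @export
population_stats <- function(values, n_min = 5L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < n_min) {
    stop(sprintf("need at least %d finite values, got %d", n_min, n))
  }
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(0.975, df = n - 1) * s / sqrt(n)
  structure(list(n = n, mean = m, sd = s,
                 band_2sd = c(lower = m - 2 * s, upper = m + 2 * s),
                 ci95 = c(lower = m - half, upper = m + half)),
            class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf("population_stats: n=%d mean=%.4g sd=%.4g  2sd=[%.4g, %.4g]  ci95=[%.4g, %.4g]\n",
              x$n, x$mean, x$sd, x$band_2sd[1], x$band_2sd[2],
              x$ci95[1], x$ci95[2]))
  invisible(x)
}
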