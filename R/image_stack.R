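#' Multi-channel 3-D image stack with physical calibration
#'
#' The central image container: one 3-D intensity array per channel
#' (dimensions y, x, z), a shared [voxel_calibration()], and the camera
#' dark offset (the constant signal present with no light, subtracted
#' before intensity quantification). Intensities are photon-count-like
#' values on the 16-bit scale; they are stored as doubles internally and
#' rounded/clamped to 0..65535 only on write.
#'
#' @param channels named list of numeric arrays, each `ny x nx x nz` (a
#'   matrix is promoted to a single-section array). All channels must share
#'   dimensions; all values must be finite and non-negative.
#' @param calibration a [voxel_calibration()].
#' @param dark_offset camera dark offset in counts (>= 0).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, calibration = voxel_calibration(),
                        dark_offset = 0) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) dim(ch) <- c(dim(ch), 1L)
    stopifnot(length(dim(ch)) == 3)
    ch
  })
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("all channels must share identical grid dimensions")
  }
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("channel '", nm, "' has non-finite or negative intensities")
    }
  }
  if (!is.finite(dark_offset) || dark_offset < 0) {
    stop("dark_offset must be finite and >= 0")
  }
  structure(list(channels = channels, calibration = calibration,
                 dark_offset = dark_offset),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %d channel(s) [%s], %d x %d px, %d z-section(s), dark offset %.1f\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3], x$dark_offset))
  invisible(x)
}

#' @rdname image_stack
#' @param stack an `image_stack`.
#' @export
n_sections <- function(stack) dim(stack$channels[[1]])[3]

get_channel <- function(stack, channel) {
  if (!channel %in% names(stack$channels)) {
    stop("unknown channel '", channel, "'; have: ",
         paste(names(stack$channels), collapse = ", "))
  }
  stack$channels[[channel]]
}

#' Read a multi-page TIFF into an image stack
#'
#' Pages are expected z-major within channel: all z-sections of the first
#' channel, then all z-sections of the second, and so on. Values are read
#' as raw 16-bit (or 8-bit) integers, not rescaled.
#'
#' @param path path to a multi-page TIFF file.
#' @param calibration a [voxel_calibration()] (TIFFs written by generic
#'   tools carry no trusted physical calibration, so it is supplied).
#' @param channels character vector of channel labels, in page order.
#' @param dark_offset camera dark offset in counts.
#' @return An `image_stack`.
#' @export
read_stack <- function(path, calibration = voxel_calibration(),
                       channels = "ch1", dark_offset = 0) {
  if (!file.exists(path)) stop("input file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_ch <- length(channels)
  if (length(pages) %% n_ch != 0) {
    stop(sprintf("page count (%d) not divisible by channel count (%d)",
                 length(pages), n_ch))
  }
  nz <- length(pages) %/% n_ch
  chans <- stats::setNames(vector("list", n_ch), channels)
  for (c_i in seq_len(n_ch)) {
    planes <- pages[((c_i - 1) * nz + 1):(c_i * nz)]
    chans[[c_i]] <- array(unlist(planes), dim = c(dim(planes[[1]]), nz))
  }
  image_stack(chans, calibration, dark_offset)
}

#' Write an image stack as a 16-bit multi-page TIFF
#'
#' Planes are written z-major within channel (the inverse of
#' [read_stack()]). Intensities are rounded and clamped to the 16-bit
#' range 0..65535.
#'
#' @param stack an `image_stack`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- list()
  for (ch in stack$channels) {
    for (z in seq_len(dim(ch)[3])) {
      plane <- pmin(pmax(round(ch[, , z]), 0), 65535)
      pages[[length(pages) + 1L]] <- plane / 65535
    }
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (!isTRUE(ok > 0)) stop("failed to write TIFF: ", path)
  invisible(path)
}

#' Tile the z-sections of one channel into a montage strip
#'
#' Lays the z-sections side by side along the x axis, in z order, with
#' pixel values unmodified — the montage representation used for drawing
#' axial line profiles across a z-stack.
#'
#' @param stack an `image_stack`.
#' @param channel channel label.
#' @return A matrix of size `ny x (nx * nz)`.
#' @export
montage_sections <- function(stack, channel) {
  ch <- get_channel(stack, channel)
  d <- dim(ch)
  matrix(ch, nrow = d[1], ncol = d[2] * d[3])
}

#' Maximum z-projection of one channel
#'
#' @param stack an `image_stack`.
#' @param channel channel label.
#' @return A matrix: per-pixel maximum over all z-sections.
#' @export
max_z_project <- function(stack, channel) {
  ch <- get_channel(stack, channel)
  out <- ch[, , 1]
  for (z in seq_len(dim(ch)[3])[-1]) out <- pmax(out, ch[, , z])
  out
}
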