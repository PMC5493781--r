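#' Write measurement records to CSV
#'
#' Accepts a data frame, a single measurement object
#' (`ring_measurement`, `gaussian_peak_fit`, `population_stats`) or a
#' homogeneous list of them. Numeric fields are written in fixed decimal
#' notation with enough digits that re-reading reproduces every value to
#' at least 6 significant digits. An empty data frame yields a
#' header-only CSV.
#'
#' @param records the records to write.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  df <- records_to_df(records)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) {
        if (!is.finite(v)) return(as.character(v))
        format(v, scientific = FALSE, digits = 12, trim = TRUE)
      }, character(1))
    }
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write table to ", path)
  invisible(path)
}

#' Read a measurement table written by [write_table()]
#' @param path CSV path.
#' @return A data frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.csv(path)
}

records_to_df <- function(records) {
  if (is.data.frame(records)) return(records)
  if (inherits(records, c("ring_measurement", "gaussian_peak_fit",
                          "population_stats"))) {
    return(record_row(records))
  }
  if (is.list(records)) {
    if (!length(records)) stop("cannot infer columns from an empty list; pass an empty data frame")
    cls <- vapply(records, function(r) class(r)[1], character(1))
    if (length(unique(cls)) != 1) stop("records must be homogeneous in type")
    return(do.call(rbind, lapply(records, record_row)))
  }
  stop("unsupported record type: ", class(records)[1])
}

record_row <- function(r) {
  if (inherits(r, "ring_measurement")) {
    data.frame(center_x_nm = r$center[1], center_y_nm = r$center[2],
               radius_nm = r$radius, diameter_nm = r$diameter,
               rms_residual_nm = r$rms_residual, n_points = r$n_points,
               source = r$source)
  } else if (inherits(r, "gaussian_peak_fit")) {
    data.frame(mu_nm = r$mu, sigma_nm = r$sigma, amplitude = r$amplitude,
               offset = r$offset, rss = r$rss, n_samples = r$n_samples)
  } else if (inherits(r, "population_stats")) {
    data.frame(n = r$n, mean = r$mean, sd = r$sd,
               band_2sd_lower = r$band_2sd[1], band_2sd_upper = r$band_2sd[2],
               ci95_lower = r$ci95[1], ci95_upper = r$ci95[2])
  } else {
    stop("unsupported record type: ", class(r)[1])
  }
}
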