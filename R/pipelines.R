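#' Pipeline drivers
#'
#' Thin, file-to-file stages that chain the measurement operations the
#' way the numbered analysis scripts (and any batch run) use them. Every
#' stage is a pure function of (inputs, config, seed): rerunning a stage
#' with the same arguments writes bit-identical outputs, and each run
#' emits one structured log line with the seed and elapsed time.
#'
#' @name pipelines
NULL

#' @describeIn pipelines Render a synthetic transverse ring to a 16-bit
#'   TIFF; the realised ground truth is written next to it as
#'   `<out_tiff>.truth.csv`.
#' @param out_tiff,out_csv output paths.
#' @param truth generator ground truth ([ring_truth()], [band_truth()] or
#'   [population_truth()] depending on the stage).
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param config a [run_config()].
#' @return The main output path, invisibly.
#' @export
pipeline_simulate_ring <- function(out_tiff, truth = ring_truth(),
                                   noise = noise_model(), seed = 1,
                                   config = run_config()) {
  t0 <- as.numeric(proc.time()["elapsed"])
  sim <- generate_transverse_ring(truth, config$calibration, noise, seed)
  write_stack(sim$stack, out_tiff)
  utils::write.csv(data.frame(outer_diameter_nm = sim$truth$outer_diameter,
                              peak_radius_nm = sim$truth$peak_radius,
                              ring_fwhm_nm = sim$truth$ring_fwhm,
                              peak_intensity = sim$truth$peak_intensity),
                   paste0(out_tiff, ".truth.csv"), row.names = FALSE)
  log_stage("simulate-ring", seed, out = out_tiff, t0 = t0)
  invisible(out_tiff)
}

#' @describeIn pipelines Measure the ring diameter in a TIFF written by
#'   [pipeline_simulate_ring()] (or any single-channel ring image) and
#'   append the measurement to a CSV.
#' @param in_tiff input TIFF path.
#' @param channel channel label(s) of the TIFF pages.
#' @export
pipeline_measure_ring <- function(in_tiff, out_csv, channel = "ring",
                                  config = run_config()) {
  t0 <- as.numeric(proc.time()["elapsed"])
  stk <- read_stack(in_tiff, config$calibration, channels = channel)
  m <- measure_ring(stk, channel, config = config)
  write_table(m, out_csv)
  log_stage("measure-ring", config$random_seed, inp = basename(in_tiff),
            diameter_nm = sprintf("%.2f", m$diameter), t0 = t0)
  invisible(out_csv)
}

#' @describeIn pipelines Render a synthetic multi-channel axial-band
#'   z-stack to TIFF (pages z-major within channel).
#' @export
pipeline_simulate_bands <- function(out_tiff, truth = band_truth(
                                      list(a = 0, b = 45)),
                                    noise = noise_model(), seed = 1,
                                    config = run_config()) {
  t0 <- as.numeric(proc.time()["elapsed"])
  sim <- generate_axial_bands(truth, config$calibration, noise, seed)
  write_stack(sim$stack, out_tiff)
  log_stage("simulate-bands", seed, out = out_tiff,
            channels = paste(names(truth$centers), collapse = "+"), t0 = t0)
  invisible(out_tiff)
}

#' @describeIn pipelines Run the axial-distance profile pipeline on a
#'   multi-channel z-stack TIFF and write per-pair distances plus the
#'   quantile summary.
#' @param channels channel labels of the TIFF, in page-block order.
#' @param line_offsets perpendicular offsets of repeated lines, px.
#' @export
pipeline_profile <- function(in_tiff, out_csv, channels,
                             config = run_config(), line_offsets = 0L) {
  t0 <- as.numeric(proc.time()["elapsed"])
  stk <- read_stack(in_tiff, config$calibration, channels = channels)
  res <- profile_pipeline(stk, config = config, line_offsets = line_offsets)
  write_table(res$distances, out_csv)
  write_table(res$summary, sub("\\.csv$", ".summary.csv", out_csv))
  log_stage("profile", config$random_seed, inp = basename(in_tiff),
            pairs = nrow(res$summary), t0 = t0)
  invisible(out_csv)
}

#' @describeIn pipelines Segment foci on a reference channel of a TIFF,
#'   dilate, quantify all channels dark-subtracted, write the per-focus
#'   table.
#' @param reference_channel centriole-marker channel used to segment.
#' @param dark_offset camera dark offset of the acquisition, counts.
#' @export
pipeline_recruit <- function(in_tiff, out_csv, channels,
                             reference_channel = channels[1],
                             dark_offset = 0, config = run_config()) {
  t0 <- as.numeric(proc.time()["elapsed"])
  stk <- read_stack(in_tiff, config$calibration, channels = channels,
                    dark_offset = dark_offset)
  ref <- pmax(max_z_project(stk, reference_channel) - dark_offset, 0)
  mask <- segment_foci(ref, config$window_px, config$offset_fraction,
                       config$min_area_px, config$max_area_px)
  mask <- dilate_labels(mask, config$dilation_radius_px)
  rec <- quantify(mask, stk)
  write_table(rec, out_csv)
  log_stage("recruit", config$random_seed, inp = basename(in_tiff),
            foci = nrow(rec), t0 = t0)
  invisible(out_csv)
}

#' @describeIn pipelines Generate a synthetic population, score every
#'   scene, and write the per-cell phenotype table plus the condition
#'   summary (`<out_csv>` and `<out_csv stem>.summary.csv`).
#' @param condition condition label.
#' @export
pipeline_score_population <- function(out_csv,
                                      truth = population_truth(),
                                      noise = noise_model(),
                                      condition = "condition",
                                      config = run_config()) {
  t0 <- as.numeric(proc.time()["elapsed"])
  pop <- generate_cell_population(truth, noise)
  calls <- score_population(pop, condition = condition,
                            min_length_um = config$min_cilium_length_um)
  write_table(calls, out_csv)
  write_table(summarize_condition(calls),
              sub("\\.csv$", ".summary.csv", out_csv))
  log_stage("score", truth$seed, n_cells = truth$n_cells,
            condition = condition, t0 = t0)
  invisible(out_csv)
}
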