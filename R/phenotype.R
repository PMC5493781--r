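#' Detect a cilium in the cilia-marker channel of a scene
#'
#' Automated surrogate for manual cilium calls: the dark-subtracted,
#' z-projected marker channel is thresholded at
#' `baseline + max(intensity_fraction * (max - baseline), min_prominence)`
#' (baseline = image median), foreground is labelled with 8-connected
#' components, and the scene is called ciliated if any component's
#' maximum Feret extent exceeds `min_length_um`. The absolute
#' `min_prominence` floor keeps pure-noise channels, whose dynamic range
#' is a few noise s.d., from producing spurious objects.
#'
#' @param scene an [image_stack()] (e.g. one scene from
#'   [generate_cell_population()]).
#' @param marker_channel cilia marker channel label.
#' @param min_length_um minimum Feret extent to call a cilium, um.
#' @param intensity_fraction threshold fraction of the dynamic range.
#' @param min_prominence absolute threshold floor above baseline, counts.
#' @return `TRUE` if a cilium is detected.
#' @export
detect_cilium <- function(scene, marker_channel = "cilia",
                          min_length_um = 1, intensity_fraction = 0.25,
                          min_prominence = 500) {
  proj <- pmax(max_z_project(scene, marker_channel) - scene$dark_offset, 0)
  base <- stats::median(proj)
  thr <- base + max(intensity_fraction * (max(proj) - base), min_prominence)
  lab <- label_components(proj > thr)
  if (max(lab) == 0) return(FALSE)
  px_um <- scene$calibration$pixel_xy / 1000
  for (id in seq_len(max(lab))) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < 3) next
    if (feret_extent_px(idx) * px_um >= min_length_um) return(TRUE)
  }
  FALSE
}

# maximum Feret extent (px) of a pixel set given as (row, col) indices;
# pairwise search restricted to the convex hull
feret_extent_px <- function(idx) {
  pts <- cbind(idx[, 2], idx[, 1])
  if (nrow(pts) > 3) {
    hull <- grDevices::chull(pts)
    pts <- pts[hull, , drop = FALSE]
  }
  max(stats::dist(pts))
}

#' Count CP110 foci within the centrosome region
#'
#' Locates the centrosome via [segment_foci()] on the centriole-marker
#' channel (dilated by `region_dilation_px`), lightly smooths the CP110
#' channel, and counts local maxima inside the region that rise more
#' than `min_prominence` counts above the channel baseline, enforcing a
#' minimum separation between accepted maxima (greedy suppression in
#' descending intensity order).
#'
#' @param scene an [image_stack()].
#' @param cp110_channel,centriole_channel channel labels.
#' @param centrosome_region optional logical matrix; computed from the
#'   centriole channel when `NULL`.
#' @param min_separation_px minimum distance between counted foci.
#' @param min_prominence required height above baseline, counts.
#' @param region_dilation_px dilation applied to the centrosome mask.
#' @return Integer number of CP110 foci.
#' @export
count_cp110_foci <- function(scene, cp110_channel = "cp110",
                             centriole_channel = "centriole",
                             centrosome_region = NULL,
                             min_separation_px = 3,
                             min_prominence = 1000,
                             region_dilation_px = 4L) {
  if (is.null(centrosome_region)) {
    ref <- pmax(max_z_project(scene, centriole_channel) - scene$dark_offset, 0)
    mask <- segment_foci(ref, window_px = 31L, offset_fraction = 0.2,
                         min_area = 2L, max_area = 400L)
    centrosome_region <- dilate_labels(mask, region_dilation_px) > 0
  }
  if (!any(centrosome_region)) return(0L)
  proj <- pmax(max_z_project(scene, cp110_channel) - scene$dark_offset, 0)
  g <- gaussian_kernel_2d(sigma = 1)
  sm <- EBImage::filter2(proj, g, boundary = "replicate")
  base <- stats::median(sm)
  # 3x3 local maxima inside the region, prominent above baseline
  is_max <- matrix(TRUE, nrow(sm), ncol(sm))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & sm >= shift_matrix(sm, dy, dx, fill = -Inf)
  }
  cand <- which(is_max & centrosome_region & (sm - base) > min_prominence,
                arr.ind = TRUE)
  if (nrow(cand) == 0) return(0L)
  ord <- order(sm[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  kept <- cand[1, , drop = FALSE]
  for (i in seq_len(nrow(cand))[-1]) {
    d <- sqrt((cand[i, 1] - kept[, 1])^2 + (cand[i, 2] - kept[, 2])^2)
    if (all(d >= min_separation_px)) kept <- rbind(kept, cand[i, ])
  }
  nrow(kept)
}

#' Score marker positivity of a scene
#'
#' Calls the RAB8A/SMO-surrogate channel positive when its brightest
#' structure rises more than `min_prominence` counts above the channel
#' baseline (mean of the top `top_px` dark-subtracted pixels, against the
#' median). Eligibility (e.g. "ciliated cells only") is the caller's
#' responsibility.
#'
#' @param scene an [image_stack()].
#' @param marker_channel channel label.
#' @param min_prominence intensity criterion, counts.
#' @param top_px number of brightest pixels averaged.
#' @return `TRUE` if the marker is present.
#' @export
score_marker_positive <- function(scene, marker_channel = "marker",
                                  min_prominence = 1000, top_px = 20) {
  proj <- pmax(max_z_project(scene, marker_channel) - scene$dark_offset, 0)
  top <- mean(sort(proj, decreasing = TRUE)[seq_len(top_px)])
  (top - stats::median(proj)) > min_prominence
}

gaussian_kernel_2d <- function(sigma, half = ceiling(3 * sigma)) {
  xs <- -half:half
  k <- exp(-outer(xs^2, xs^2, "+") / (2 * sigma^2))
  k / sum(k)
}

#' Score every scene of a synthetic population
#'
#' Runs [detect_cilium()], [count_cp110_foci()] and (for ciliated cells)
#' [score_marker_positive()] on each scene, yielding the per-cell
#' phenotype table consumed by [summarize_condition()].
#'
#' @param population result of [generate_cell_population()], or a list of
#'   scenes.
#' @param condition condition label attached to every cell.
#' @param min_length_um minimum cilium length passed to [detect_cilium()].
#' @return A data frame with `cell_id`, `ciliated`, `n_cp110_foci`,
#'   `marker_positive` (`NA` when ineligible) and `condition`.
#' @export
score_population <- function(population, condition = "condition",
                             min_length_um = 1) {
  scenes <- if (!is.null(population$scenes)) population$scenes else population
  n <- length(scenes)
  ciliated <- logical(n)
  n_foci <- integer(n)
  marker <- rep(NA, n)
  for (i in seq_len(n)) {
    sc <- scenes[[i]]
    ciliated[i] <- detect_cilium(sc, min_length_um = min_length_um)
    n_foci[i] <- count_cp110_foci(sc)
    if (ciliated[i]) marker[i] <- score_marker_positive(sc)
  }
  data.frame(cell_id = seq_len(n), ciliated = ciliated,
             n_cp110_foci = n_foci, marker_positive = marker,
             condition = condition)
}

#' Summarise phenotype percentages for one condition
#'
#' Percentages of ciliated cells, cells with exactly two CP110 foci, and
#' marker-positive cells among eligible cells (those with a non-missing
#' `marker_positive` call). Denominators are reported alongside; a
#' percentage with zero eligible cells is `NA`, not 0.
#'
#' @param phenotypes data frame as from [score_population()] (columns
#'   `ciliated`, `n_cp110_foci`, `marker_positive`, optionally
#'   `condition`).
#' @return A one-row data frame with class `condition_summary`.
#' @export
summarize_condition <- function(phenotypes) {
  stopifnot(nrow(phenotypes) >= 1)
  n <- nrow(phenotypes)
  n_elig <- sum(!is.na(phenotypes$marker_positive))
  out <- data.frame(
    condition = if ("condition" %in% names(phenotypes)) {
      phenotypes$condition[1]
    } else "condition",
    n_cells = n,
    percent_ciliated = 100 * sum(phenotypes$ciliated) / n,
    percent_two_foci = 100 * sum(phenotypes$n_cp110_foci == 2) / n,
    n_marker_eligible = n_elig,
    percent_marker_positive = if (n_elig > 0) {
      100 * sum(phenotypes$marker_positive, na.rm = TRUE) / n_elig
    } else NA_real_)
  class(out) <- c("condition_summary", class(out))
  out
}

#' Two-tailed unpaired Student t-test
#'
#' Classical pooled-variance two-sample t-test with
#' `df = n_a + n_b - 2` and a two-sided p-value (Welch's unequal-variance
#' form behind `welch = TRUE`). Degenerate inputs are resolved before
#' testing: zero pooled variance with equal means gives `t = 0, p = 1`;
#' zero pooled variance with unequal means is an error.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param welch use the Welch test instead of the pooled-variance test.
#' @return A list with `t`, `df` and `p`.
#' @export
two_tailed_ttest <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values")
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1))
    }
    stop("zero variance in both groups with unequal means: t undefined")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Significance stars for a p-value
#'
#' Default key: `*` for p < 0.05, `**` for p < 0.01. Figure-specific
#' keys (e.g. a single star meaning p < 0.01) can be supplied as the
#' decreasing threshold vector.
#'
#' @param p p-value.
#' @param key decreasing vector of thresholds; the i-th threshold met
#'   earns i stars.
#' @return A string of stars (possibly empty).
#' @export
significance_stars <- function(p, key = c(0.05, 0.01)) {
  strrep("*", sum(p < key))
}

#' Replicate-level comparison of condition percentages
#'
#' Compares each condition's replicate percentages to a reference
#' condition with the two-tailed unpaired Student t-test, annotating
#' significance stars. The standard use is testing whether re-expression
#' of a construct rescues a knockout's ciliation percentage.
#'
#' @param replicates data frame with columns `condition` and `percent`
#'   (one row per replicate); every condition needs >= 2 replicates.
#' @param reference condition to test the others against (default: first
#'   condition in the table).
#' @param star_key significance key for [significance_stars()].
#' @return A data frame with one row per non-reference condition:
#'   means of both groups, `t`, `df`, `p` and `stars`.
#' @export
rescue_comparison <- function(replicates, reference = NULL,
                              star_key = c(0.05, 0.01)) {
  stopifnot(all(c("condition", "percent") %in% names(replicates)))
  groups <- split(replicates$percent, replicates$condition)
  if (any(lengths(groups) < 2)) {
    stop("every condition needs at least 2 replicates")
  }
  reference <- reference %||% as.character(replicates$condition[1])
  if (!reference %in% names(groups)) stop("unknown reference condition")
  others <- setdiff(names(groups), reference)
  rows <- lapply(others, function(cond) {
    tt <- two_tailed_ttest(groups[[cond]], groups[[reference]])
    data.frame(condition = cond, reference = reference,
               mean_condition = mean(groups[[cond]]),
               mean_reference = mean(groups[[reference]]),
               t = tt$t, df = tt$df, p = tt$p,
               stars = significance_stars(tt$p, star_key))
  })
  do.call(rbind, rows)
}
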