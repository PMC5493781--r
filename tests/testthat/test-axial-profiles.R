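test_that("montage tiles z-sections side by side in z order", {
  arr <- array(0, c(64, 64, 25))
  for (z in 1:25) arr[, , z] <- z
  stk <- image_stack(list(a = arr))
  m <- montage_sections(stk, "a")
  expect_equal(dim(m), c(64, 1600))
  expect_true(all(m[, 1:64] == 1))
  expect_true(all(m[, 1537:1600] == 25))

  one <- image_stack(list(a = matrix(1:16, 4, 4)))
  expect_equal(montage_sections(one, "a"), matrix(1:16, 4, 4))
  expect_error(montage_sections(one, "zz"), "unknown channel")

  const <- image_stack(list(a = array(3, c(5, 5, 4))))
  expect_true(all(montage_sections(const, "a") == 3))
})

test_that("sample_profile interpolates and averages as specified", {
  img <- matrix(7, 21, 21)
  ln <- line_spec(c(2, 10), c(18, 10), sampling_step = 40,
                  averaging_width = 3)
  prof <- sample_profile(img, ln)
  expect_true(all(prof$intensities == 7))
  expect_equal(diff(prof$positions)[1], 40)

  # profile across a rendered Gaussian band peaks at the band centre
  xs <- 0:20
  band <- outer(rep(1, 21), exp(-(xs - 10.25)^2 / (2 * 4)))
  p2 <- sample_profile(band, line_spec(c(0, 10), c(20, 10), 40))
  expect_lt(abs(p2$positions[which.max(p2$intensities)] - 10.25 * 40), 40)

  # widths 1 and 5 agree along a symmetry axis of a y-symmetric image
  sym <- outer(exp(-(xs - 10)^2 / 8), exp(-(xs - 10)^2 / 18))
  n1 <- sample_profile(sym, line_spec(c(2, 10), c(18, 10), 40,
                                      averaging_width = 1))
  n5 <- sample_profile(sym, line_spec(c(2, 10), c(18, 10), 40,
                                      averaging_width = 5))
  expect_equal(n1$intensities / max(n1$intensities),
               n5$intensities / max(n5$intensities), tolerance = 1e-10)

  expect_error(sample_profile(img, line_spec(c(-5, 10), c(18, 10), 40)),
               "inside the image")
})

test_that("normalize_max scales to unit maximum, preserves shape, and is idempotent", {
  p <- line_profile(c(0, 10, 20, 30, 40), c(2, 4, 8, 4, 2))
  n <- normalize_max(p)
  expect_equal(n$intensities, c(0.25, 0.5, 1, 0.5, 0.25))
  expect_identical(normalize_max(n), n)
  for (s in 1:10) {
    set.seed(s)
    q <- line_profile(seq(0, 500, 50), stats::runif(11, 0.1, 5))
    expect_equal(normalize_max(normalize_max(q)), normalize_max(q))
  }
  expect_error(normalize_max(line_profile(1:5, rep(0, 5))), "all-zero")
})

test_that("find_peak_regions applies the 30%-of-maximum rule", {
  x <- seq(0, 3000, by = 25)
  two_peaks <- function(a2) {
    line_profile(x, exp(-(x - 700)^2 / (2 * 120^2)) +
                   a2 * exp(-(x - 2300)^2 / (2 * 120^2)))
  }
  expect_length(find_peak_regions(two_peaks(0.25)), 1)
  expect_length(find_peak_regions(two_peaks(0.50)), 2)

  single <- line_profile(x, exp(-(x - 1500)^2 / (2 * 150^2)))
  regs <- find_peak_regions(single)
  expect_length(regs, 1)
  amax <- which.max(single$intensities)
  expect_true(regs[[1]][1] <= amax && amax <= regs[[1]][2])
})

test_that("peak regions are disjoint, ordered, and contain the argmax (property)", {
  for (s in 1:25) {
    set.seed(s)
    x <- seq(0, 3000, by = 60)
    y <- rep(0, length(x))
    for (k in seq_len(sample(1:4, 1))) {
      y <- y + stats::runif(1, 0.2, 1) *
        exp(-(x - stats::runif(1, 200, 2800))^2 / (2 * stats::runif(1, 60, 200)^2))
    }
    prof <- line_profile(x, y + 0.01)
    regs <- find_peak_regions(prof)
    amax <- which.max(prof$intensities)
    expect_true(any(vapply(regs, function(r) r[1] <= amax && amax <= r[2],
                           logical(1))))
    if (length(regs) > 1) {
      starts <- vapply(regs, `[`, 0, 1)
      ends <- vapply(regs, `[`, 0, 2)
      expect_true(all(starts[-1] > ends[-length(ends)]))
    }
  }
})

test_that("fit_gaussian recovers exact parameters on noiseless samples", {
  x <- seq(-400, 600, by = 50)
  y <- 2.5 * exp(-(x - 100)^2 / (2 * 150^2)) + 0.2
  fit <- fit_gaussian(line_profile(x, y))
  expect_lt(abs(fit$mu - 100), 0.01)
  expect_lt(abs(fit$sigma - 150), 0.1)
  expect_lt(abs(fit$amplitude - 2.5), 0.01)
  expect_lt(abs(fit$offset - 0.2), 0.01)
  expect_lt(fit$rss, 1e-12)
})

test_that("fit_gaussian centres a symmetric triangular peak at its apex", {
  x <- seq(0, 1000, by = 50)
  y <- pmax(0, 1 - abs(x - 500) / 300) + 0.05
  fit <- fit_gaussian(line_profile(x, y))
  expect_lt(abs(fit$mu - 500), 1e-6)
})

test_that("fit_gaussian needs at least 4 samples and errors usefully on flat data", {
  p <- line_profile(seq(0, 400, 100), c(1, 2, 5, 2, 1))
  expect_error(fit_gaussian(p, c(1, 3)), "at least 4")
  flat <- line_profile(seq(0, 400, 100), rep(2, 5))
  expect_error(fit_gaussian(flat), "flat region")
})

test_that("fits match the dense grid-search oracle on noisy profiles", {
  worse <- 0
  for (s in 1:30) {
    prof <- noisy_gaussian_profile(s)
    regs <- find_peak_regions(prof)
    amax <- which.max(prof$intensities)
    reg <- Filter(function(r) r[1] <= amax && amax <= r[2], regs)[[1]]
    reg <- c(max(1, reg[1] - 2), min(length(prof$positions), reg[2] + 2))
    fit <- fit_gaussian(prof, reg)
    idx <- reg[1]:reg[2]
    orc <- grid_search_gaussian(prof$positions[idx], prof$intensities[idx],
                                mu_grid = seq(1450, 1550, by = 0.5),
                                sigma_grid = seq(100, 220, by = 1))
    expect_lt(abs(fit$mu - orc$mu), 0.5 + 1e-9)
    expect_lt(abs(fit$sigma - orc$sigma), 1 + 1e-9)
    if (fit$rss > orc$rss * 1.01) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("axial_distance is the unsigned peak separation", {
  x <- seq(0, 3000, 125)
  f1 <- fit_gaussian(line_profile(x, exp(-(x - 1500)^2 / (2 * 155^2)) + 0.01))
  expect_equal(axial_distance(f1, f1), 0)
  for (s in 1:10) {
    set.seed(s)
    mu2 <- stats::runif(1, 800, 2200)
    f2 <- fit_gaussian(line_profile(x, exp(-(x - mu2)^2 / (2 * 155^2)) + 0.01))
    expect_equal(axial_distance(f1, f2), axial_distance(f2, f1))
    expect_gte(axial_distance(f1, f2), 0)
  }
})

test_that("distances are invariant to positive rescaling of a profile (property)", {
  sim <- generate_axial_bands(band_truth(list(a = 0, b = 45)),
                              noise = no_noise(background = 50), seed = 1)
  base <- profile_pipeline(sim$stack)$distances$distance_nm
  scaled <- sim
  scaled$stack$channels$a <- scaled$stack$channels$a * 17.3
  expect_equal(profile_pipeline(scaled$stack)$distances$distance_nm, base,
               tolerance = 1e-6)
})

test_that("profile_pipeline recovers a three-channel axial geometry", {
  tr <- band_truth(list(p = 0, q = 45, r = 100))
  sim <- generate_axial_bands(tr, noise = no_noise(background = 50), seed = 1)
  res <- profile_pipeline(sim$stack)
  d <- res$distances
  expect_equal(d$distance_nm[d$pair == "p-q"], 45, tolerance = 0.5)
  expect_equal(d$distance_nm[d$pair == "p-r"], 100, tolerance = 0.5)
  expect_equal(d$distance_nm[d$pair == "q-r"], 55, tolerance = 0.5)
})

test_that("a duplicated channel measures zero distance and replicate lines give quantiles", {
  tr <- band_truth(list(a = 10, b = 10))
  sim <- generate_axial_bands(tr, noise = noise_model(), seed = 2)
  res <- profile_pipeline(sim$stack,
                          line_offsets = seq(-0.7, 0.7, length.out = 15))
  expect_equal(nrow(res$distances), 15)
  expect_equal(res$summary$n, 15)
  expect_true(res$summary$q25_nm <= res$summary$median_nm)
  expect_true(res$summary$median_nm <= res$summary$q75_nm)
  expect_lt(res$summary$median_nm, 5)
})

test_that("axial distance estimation is nearly unbiased and precise across separations (property)", {
  for (sep in c(30, 100)) {
    d <- vapply(1:25, function(s) {
      sim <- generate_axial_bands(band_truth(list(a = 0, b = sep)),
                                  noise = noise_model(), seed = s)
      profile_pipeline(sim$stack)$distances$distance_nm
    }, numeric(1))
    expect_lt(abs(mean(d) - sep), 2)
    expect_lt(stats::sd(d), 8)
  }
})
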