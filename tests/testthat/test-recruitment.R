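test_that("segment_foci finds rendered foci on a flat background and none on a uniform image", {
  img <- matrix(10, 64, 64)
  img <- img + centriolr:::render_spot(64, c(20, 20), 500, 1.5) +
    centriolr:::render_spot(64, c(44, 40), 500, 1.5)
  mask <- segment_foci(img, window_px = 31, min_area = 2)
  expect_equal(max(mask), 2)
  expect_warning(m0 <- segment_foci(matrix(5, 64, 64), window_px = 31),
                 "no foci")
  expect_equal(max(m0), 0)
})

test_that("segmentation labels are ordered by descending integrated intensity", {
  img <- matrix(0, 64, 64)
  img <- img + centriolr:::render_spot(64, c(15, 15), 300, 1.5) +
    centriolr:::render_spot(64, c(45, 45), 900, 1.5)
  mask <- segment_foci(img, window_px = 31, min_area = 2)
  s1 <- sum(img[mask == 1]); s2 <- sum(img[mask == 2])
  expect_gt(s1, s2)
})

test_that("focus counts recover generator truth across noisy scenes", {
  hits <- 0
  n_scenes <- 30
  for (s in seq_len(n_scenes)) {
    pop <- generate_cell_population(population_truth(n_cells = 1, seed = s))
    ref <- pmax(max_z_project(pop$scenes[[1]], "centriole") -
                  pop$scenes[[1]]$dark_offset, 0)
    mask <- segment_foci(ref, window_px = 31, offset_fraction = 0.2,
                         min_area = 2)
    if (max(mask) == 2) hits <- hits + 1
  }
  expect_gte(hits / n_scenes, 0.95)
})

test_that("a single pixel dilated by radius 3 becomes the 29-pixel discrete disc", {
  m <- matrix(0L, 15, 15); m[8, 8] <- 1L
  d <- dilate_labels(m, 3)
  expect_equal(sum(d == 1), disc_pixel_count(3))
  expect_equal(sum(d == 1), 29)
  # every grown pixel is within radius 3 of the seed
  idx <- which(d == 1, arr.ind = TRUE)
  expect_true(all((idx[, 1] - 8)^2 + (idx[, 2] - 8)^2 <= 9))
})

test_that("dilation is monotone, keeps original labels, and radius 0 is the identity", {
  for (s in 1:20) {
    m <- random_label_mask(30, sample(1:4, 1), seed = s)
    expect_identical(dilate_labels(m, 0), m)
    d <- dilate_labels(m, 3)
    expect_true(all(d[m > 0] == m[m > 0]))
    for (id in seq_len(max(m))) {
      expect_true(all(d[m == id] == id))
      expect_gte(sum(d == id), sum(m == id))
    }
  }
})

test_that("overlapping dilations resolve to the nearest label, ties to the lower id", {
  m <- matrix(0L, 9, 15)
  m[5, 4] <- 1L; m[5, 10] <- 2L
  d <- dilate_labels(m, 3)
  expect_equal(d[5, 6], 1L)  # distance 2 vs 4
  expect_equal(d[5, 8], 2L)  # distance 4 vs 2
  expect_equal(d[5, 7], 1L)  # tie at distance 3 -> lower id
})

test_that("composed dilations are bounded by the single-disc dilations (property)", {
  for (r in 1:3) for (s in 1:(4 - r)) {
    m <- matrix(0L, 21, 21); m[11, 11] <- 1L
    comp <- dilate_labels(dilate_labels(m, r), s)
    lower <- dilate_labels(m, max(r, s))
    upper <- dilate_labels(m, r + s)
    expect_true(all(comp[lower == 1] == 1))
    expect_true(all(upper[comp == 1] == 1))
  }
})

test_that("quantify matches the closed form on uniform labels", {
  mask <- matrix(0L, 10, 10); mask[3:5, 3:6] <- 1L
  stk <- image_stack(list(a = matrix(150, 10, 10)), dark_offset = 50)
  rec <- quantify(mask, stk)
  expect_equal(rec$mean_a, 100)
  expect_equal(rec$integrated_a, 100 * 12)
  # v == dark gives exactly zero
  stk0 <- image_stack(list(a = matrix(50, 10, 10)), dark_offset = 50)
  expect_equal(quantify(mask, stk0)$mean_a, 0)
  # empty mask -> empty record list
  expect_equal(nrow(quantify(matrix(0L, 10, 10), stk)), 0)
})

test_that("quantify equals a naive per-pixel loop oracle exactly", {
  set.seed(5)
  mask <- random_label_mask(20, 3, seed = 5)
  img <- matrix(stats::runif(400, 0, 300), 20, 20)
  stk <- image_stack(list(a = img), dark_offset = 120)
  rec <- quantify(mask, stk)
  orc <- quantify_loop_oracle(mask, img, 120)
  expect_equal(rec$area_px, orc$area)
  expect_equal(rec$mean_a, orc$mean)
  expect_equal(rec$integrated_a, orc$integrated)
  expect_equal(rec$integrated_a, rec$mean_a * rec$area_px,
               tolerance = 1e-6)
})

test_that("quantify is linear under joint scaling of image and dark offset", {
  mask <- random_label_mask(20, 2, seed = 9)
  img <- matrix(stats::runif(400, 100, 500), 20, 20)
  r1 <- quantify(mask, image_stack(list(a = img), dark_offset = 80))
  r3 <- quantify(mask, image_stack(list(a = 3 * img), dark_offset = 240))
  expect_equal(r3$mean_a, 3 * r1$mean_a)
  expect_equal(r3$integrated_a, 3 * r1$integrated_a)
})

test_that("population_stats matches the closed-form t interval", {
  ps <- population_stats(1:5)
  expect_equal(ps$mean, 3)
  expect_equal(ps$sd, sqrt(2.5), tolerance = 1e-6)
  half <- stats::qt(0.975, 4) * ps$sd / sqrt(5)
  expect_equal(unname(ps$ci95["upper"] - ps$mean), half)
  expect_equal(round(half, 4), 1.9632)
  # degenerate constant sample
  cs <- population_stats(rep(4, 6))
  expect_equal(unname(cs$band_2sd), c(4, 4))
  expect_equal(unname(cs$ci95), c(4, 4))
  expect_error(population_stats(1:3), "at least 5")
  # CI nested inside the 2-sd band for n >= 5
  for (s in 1:10) {
    set.seed(s)
    v <- stats::rnorm(sample(5:50, 1))
    ps <- population_stats(v)
    expect_gte(ps$ci95["lower"], ps$band_2sd["lower"])
    expect_lte(ps$ci95["upper"], ps$band_2sd["upper"])
  }
})

test_that("a 5%-of-control signal falls below the control 2-sd band almost surely", {
  set.seed(77)
  below <- 0
  for (rep in 1:200) {
    wt <- stats::rnorm(30, mean = 1000, sd = 200)   # CV 20%
    ko <- stats::rnorm(1, mean = 50, sd = 10)
    if (ko < population_stats(wt)$band_2sd["lower"]) below <- below + 1
  }
  expect_gte(below / 200, 0.99)
})

test_that("channel intensity ratios are recovered end-to-end on two-channel foci", {
  for (f in c(0.1, 0.5, 1.0)) {
    ratios <- vapply(1:15, function(s) {
      set.seed(s)
      ctr1 <- c(14, 14) + stats::runif(2, -2, 2)
      ctr2 <- c(34, 34) + stats::runif(2, -2, 2)
      sig1 <- centriolr:::render_spot(48, ctr1, 10000, 1.3) +
        centriolr:::render_spot(48, ctr2, 10000, 1.3)
      noise <- noise_model(background = 0, dark_offset = 100,
                           gaussian_sd = 5)
      ch1 <- centriolr:::apply_noise(sig1, noise)
      ch2 <- centriolr:::apply_noise(f * sig1, noise)
      stk <- image_stack(list(a = ch1, b = ch2), dark_offset = 100)
      mask <- segment_foci(pmax(ch1 - 100, 0), window_px = 31,
                           offset_fraction = 0.2, min_area = 2)
      rec <- quantify(dilate_labels(mask, 3), stk)
      sum(rec$integrated_b) / sum(rec$integrated_a)
    }, numeric(1))
    expect_lt(abs(mean(ratios) - f) / f, 0.05)
  }
})
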