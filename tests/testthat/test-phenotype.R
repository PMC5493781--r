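test_that("detect_cilium is truth-accurate on rendered scenes and rejects empty channels", {
  pop <- generate_cell_population(population_truth(n_cells = 30,
                                                   p_ciliated = 0.5,
                                                   seed = 12))
  calls <- vapply(pop$scenes, detect_cilium, logical(1))
  expect_gte(mean(calls == pop$labels$ciliated), 0.98)

  empty <- image_stack(list(cilia = matrix(50, 96, 96)),
                       centriolr:::scene_calibration(), dark_offset = 0)
  expect_false(detect_cilium(empty))
  expect_error(detect_cilium(pop$scenes[[1]], marker_channel = "nope"),
               "unknown channel")
})

test_that("count_cp110_foci matches the rendered focus count", {
  two <- generate_cell_population(population_truth(n_cells = 10,
                                                   p_two_cp110_foci = 1,
                                                   seed = 5))
  expect_true(all(vapply(two$scenes, count_cp110_foci, integer(1)) == 2L))
  one <- generate_cell_population(population_truth(n_cells = 10,
                                                   p_two_cp110_foci = 0,
                                                   seed = 6))
  expect_true(all(vapply(one$scenes, count_cp110_foci, integer(1)) == 1L))
  # empty channel -> 0
  sc <- two$scenes[[1]]
  sc$channels$cp110 <- array(100, c(96, 96, 1))
  expect_equal(count_cp110_foci(sc), 0L)
})

test_that("summarize_condition reproduces exact counting on random tables", {
  df <- data.frame(ciliated = rep(c(TRUE, FALSE), c(240, 60)),
                   n_cp110_foci = rep(1L, 300),
                   marker_positive = NA)
  s <- summarize_condition(df)
  expect_equal(s$percent_ciliated, 80)
  expect_true(is.na(s$percent_marker_positive))

  none <- data.frame(ciliated = rep(FALSE, 100), n_cp110_foci = 1L,
                     marker_positive = NA)
  s0 <- summarize_condition(none)
  expect_equal(s0$percent_ciliated, 0)
  expect_true(is.na(s0$percent_marker_positive))

  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:200, 1)
    tab <- data.frame(
      ciliated = stats::runif(n) < 0.6,
      n_cp110_foci = sample(0:2, n, TRUE),
      marker_positive = ifelse(stats::runif(n) < 0.5, stats::runif(n) < 0.4, NA))
    s <- summarize_condition(tab)
    expect_equal(s$n_cells, n)
    expect_equal(s$percent_ciliated, 100 * sum(tab$ciliated) / n)
    expect_equal(s$percent_two_foci, 100 * sum(tab$n_cp110_foci == 2) / n)
    elig <- !is.na(tab$marker_positive)
    if (any(elig)) {
      expect_equal(s$percent_marker_positive,
                   100 * sum(tab$marker_positive[elig]) / sum(elig))
    }
    expect_true(s$percent_ciliated >= 0 && s$percent_ciliated <= 100)
    expect_equal(sum(tab$ciliated) + sum(!tab$ciliated), n)
  }
})

test_that("two_tailed_ttest matches the closed-form pooled computation", {
  r <- two_tailed_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(round(r$t, 4), -1.2247)
  expect_equal(round(r$p, 4), 0.2879)
  expect_equal(r$df, 4)

  same <- two_tailed_ttest(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  ident <- two_tailed_ttest(rep(2, 3), rep(2, 4))
  expect_equal(ident$p, 1)
  expect_error(two_tailed_ttest(rep(1, 3), rep(2, 3)), "zero variance")
  expect_error(two_tailed_ttest(1, c(1, 2)), "at least 2")
})

test_that("the t-test is invariant under a common affine transformation", {
  for (s in 1:10) {
    set.seed(s)
    a <- stats::rnorm(8); b <- stats::rnorm(10, mean = 0.5)
    p0 <- two_tailed_ttest(a, b)$p
    p1 <- two_tailed_ttest(3.7 * a - 11, 3.7 * b - 11)$p
    expect_equal(p0, p1, tolerance = 1e-12)
  }
})

test_that("null calibration: rejection rate at alpha = 0.05 is nominal", {
  set.seed(123)
  n_rep <- 10000
  a <- matrix(stats::rnorm(5 * n_rep), 5)
  b <- matrix(stats::rnorm(5 * n_rep), 5)
  # vectorised pooled t for speed; spot-check equality with the function
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  sp <- sqrt((4 * va + 4 * vb) / 8)
  t <- (ma - mb) / (sp * sqrt(2 / 5))
  p <- 2 * stats::pt(-abs(t), df = 8)
  for (k in c(1, 500, 9999)) {
    expect_equal(two_tailed_ttest(a[, k], b[, k])$p, p[k], tolerance = 1e-10)
  }
  expect_gt(mean(p < 0.05), 0.045)
  expect_lt(mean(p < 0.05), 0.055)
})

test_that("significance stars follow the default and figure-specific keys", {
  expect_equal(significance_stars(0.2), "")
  expect_equal(significance_stars(0.03), "*")
  expect_equal(significance_stars(0.005), "**")
  expect_equal(significance_stars(0.03, key = 0.01), "")
})

test_that("rescue_comparison flags large replicate differences and not identical ones", {
  reps <- data.frame(condition = rep(c("KO", "KO+GFP-CEP19"), each = 3),
                     percent = c(10, 12, 14, 75, 80, 85))
  out <- rescue_comparison(reps, reference = "KO")
  expect_lt(out$p, 0.01)
  expect_equal(out$stars, "**")

  same <- data.frame(condition = rep(c("a", "b"), each = 3),
                     percent = rep(c(50, 55, 60), 2))
  expect_equal(rescue_comparison(same, reference = "a")$stars, "")
  expect_error(rescue_comparison(data.frame(condition = c("a", "b"),
                                            percent = c(1, 2))),
               "at least 2 replicates")
})

test_that("a null rescue contrast stars at roughly the alpha rate", {
  set.seed(9)
  stars <- vapply(1:400, function(i) {
    a <- stats::rnorm(4, 70, 5); b <- stats::rnorm(4, 70, 5)
    reps <- data.frame(condition = rep(c("x", "y"), each = 4),
                       percent = c(a, b))
    nchar(rescue_comparison(reps, reference = "x")$stars) > 0
  }, logical(1))
  expect_gt(mean(stars), 0.02)
  expect_lt(mean(stars), 0.09)
})

test_that("scoring recovers generator probabilities within binomial margins (small n)", {
  tr <- population_truth(n_cells = 60, p_ciliated = 0.7,
                         p_two_cp110_foci = 0.3,
                         p_marker_positive_given_cilium = 0.7, seed = 42)
  pop <- generate_cell_population(tr)
  calls <- score_population(pop)
  s <- summarize_condition(calls)
  margin <- function(p) 100 * 1.96 * sqrt(p * (1 - p) / 60)
  expect_lt(abs(s$percent_ciliated - 70), margin(0.7))
  expect_lt(abs(s$percent_two_foci - 30), margin(0.3))
  # and the detector agrees with the labels nearly always
  expect_gte(mean(calls$ciliated == pop$labels$ciliated), 0.98)
  expect_gte(mean(calls$n_cp110_foci == pop$labels$n_cp110_foci), 0.95)
})
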