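# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (dense grids, per-pixel loops, direct enumeration) so
# they share no code path with the implementation they check.

# Dense grid search for the best 1-D Gaussian + offset fit. For every
# (mu, sigma) grid node the optimal amplitude/offset pair is the exact
# linear least-squares solution; ties broken by smallest mu.
grid_search_gaussian <- function(x, y, mu_grid, sigma_grid) {
  best <- list(rss = Inf, mu = Inf)
  n <- length(x)
  sy <- sum(y)
  for (s in sigma_grid) {
    B <- exp(-outer(x, mu_grid, "-")^2 / (2 * s^2))  # n x n_mu
    sb <- colSums(B)
    sbb <- colSums(B^2)
    sby <- as.numeric(crossprod(B, y))
    det <- n * sbb - sb^2
    A <- (n * sby - sb * sy) / det
    C <- (sy - A * sb) / n
    # project onto the physical model class (A >= 0, C >= 0), as the
    # fitted model is bounded there
    neg_C <- C < 0
    A[neg_C] <- pmax(sby[neg_C] / sbb[neg_C], 0)
    C[neg_C] <- 0
    neg_A <- A < 0
    A[neg_A] <- 0
    C[neg_A] <- max(sy / n, 0)
    # rss = sum((y - A*B - C)^2)
    rss <- sum(y^2) + A^2 * sbb + n * C^2 -
      2 * A * sby - 2 * C * sy + 2 * A * C * sb
    rss[!is.finite(rss)] <- Inf
    # best node of this sigma row; ties at equal rss go to the smaller mu
    # (mu_grid is increasing, which.min picks the first)
    k <- which.min(rss)
    if (rss[k] < best$rss - 1e-12 ||
        (abs(rss[k] - best$rss) <= 1e-12 && mu_grid[k] < best$mu)) {
      best <- list(mu = mu_grid[k], sigma = s, A = A[k], C = C[k],
                   rss = rss[k])
    }
  }
  best
}

# Direct Nelder-Mead minimisation of the geometric circle loss, from a
# centroid-based start; independent of the package's Kasa + Gauss-Newton.
circle_fit_oracle <- function(pts) {
  sse <- function(par) {
    sum((sqrt((pts[, 1] - par[1])^2 + (pts[, 2] - par[2])^2) - par[3])^2)
  }
  ctr <- colMeans(pts)
  r0 <- mean(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2))
  o <- stats::optim(c(ctr, r0), sse, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))
  list(center = o$par[1:2], radius = o$par[3], sse = o$value)
}

# Naive per-pixel quantification loop
quantify_loop_oracle <- function(mask, image, dark_offset) {
  out <- NULL
  for (id in seq_len(max(mask))) {
    vals <- c()
    for (i in seq_len(nrow(mask))) {
      for (j in seq_len(ncol(mask))) {
        if (mask[i, j] == id) {
          vals <- c(vals, max(0, image[i, j] - dark_offset))
        }
      }
    }
    out <- rbind(out, data.frame(focus_id = id, area = length(vals),
                                 mean = mean(vals), integrated = sum(vals)))
  }
  out
}

# number of integer pixels with dx^2 + dy^2 <= r^2
disc_pixel_count <- function(r) {
  sum(outer((-r:r)^2, (-r:r)^2, "+") <= r^2)
}

# random label mask with a few seeded blobs
random_label_mask <- function(size, n_labels, seed) {
  set.seed(seed)
  m <- matrix(0L, size, size)
  for (id in seq_len(n_labels)) {
    cy <- sample(3:(size - 2), 1)
    cx <- sample(3:(size - 2), 1)
    m[cy + sample(-1:1, 2, TRUE), cx + sample(-1:1, 2, TRUE)] <- id
  }
  m
}

# quick synthetic 1-D Gaussian profile with noise, axial-like sampling
noisy_gaussian_profile <- function(seed, mu = 1500, sigma = 155, A = 1,
                                   C = 0.05, noise_sd = 0.02, step = 125,
                                   len = 3000) {
  set.seed(seed)
  x <- seq(0, len, by = step)
  y <- pmax(A * exp(-(x - mu)^2 / (2 * sigma^2)) + C +
              stats::rnorm(length(x), sd = noise_sd), 0)
  line_profile(x, y)
}
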