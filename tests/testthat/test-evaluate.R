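# Direction binning, histogram machinery, error metrics, floors.

test_that("direction bins follow the half-open wedge rule", {
  expect_equal(bin_timesteps(10, angles = TRUE), 0)
  expect_equal(bin_timesteps(22.5, angles = TRUE), 45)
  expect_equal(bin_timesteps(359, angles = TRUE), 0)
  expect_equal(bin_timesteps(202.4, angles = TRUE), 180)
  # velocity form flags zero velocities
  v <- rbind(c(1, 0), c(0, 0), c(-1, -1))
  b <- bin_timesteps(v)
  expect_equal(b[1], 0)
  expect_true(is.na(b[2]))
  expect_equal(b[3], 225)
  # 1e4 random angles vs a modular-arithmetic oracle
  set.seed(2)
  a <- runif(1e4, 0, 360)
  oracle <- (round(a / 45) %% 8) * 45
  expect_equal(bin_timesteps(a, angles = TRUE), oracle)
})

test_that("cross-validated width is near the asymptotic optimum and scales", {
  set.seed(3)
  x <- rnorm(1e4)
  h <- select_bin_width(x)
  h_star <- 3.49 * sd(x) * length(x)^(-1 / 3)
  expect_gt(h, h_star / 2)
  expect_lt(h, h_star * 2)
  expect_equal(select_bin_width(5 * x), 5 * h, tolerance = 1e-12)
  expect_error(select_bin_width(rep(1, 500)), "degenerate")
})

test_that("LOO risk prefers a width that avoids empty-bin fragmentation", {
  # two points close together: a width spanning both has lower risk than a
  # width isolating each in its own narrow bin
  x <- c(0.40, 0.45)
  expect_lt(histogram_cv_risk(x, 1), histogram_cv_risk(x, 0.04))
})

test_that("histogram error is the half total-variation distance", {
  set.seed(4)
  x <- rnorm(1000)
  h <- 0.3
  y <- null_histogram(x, h)
  expect_equal(sum(y$mass), 1)
  expect_equal(histogram_error(y, y), 0)

  a <- runif(500); b <- runif(500) + 2   # disjoint supports
  lo <- min(a, b); hi <- max(a, b)
  expect_equal(histogram_error(null_histogram(a, 0.25, lo, hi),
                               null_histogram(b, 0.25, lo, hi)), 1)

  y2 <- structure(list(edges = c(0, 1, 2), mass = c(0.5, 0.5), n = 2),
                  class = "null_histogram")
  yh <- structure(list(edges = c(0, 1, 2), mass = c(1, 0), n = 2),
                  class = "null_histogram")
  expect_equal(histogram_error(y2, yh), 0.5)
  # symmetry and bounds
  expect_equal(histogram_error(yh, y2), 0.5)
  expect_error(histogram_error(y2, null_histogram(a, 0.25)), "identical edges")
})

test_that("mean error is the euclidean distance", {
  expect_equal(mean_error(rep(1, 8), rep(1, 8)), 0)
  expect_equal(mean_error(c(3, 4, rep(0, 6)), rep(0, 8)), 5)
  expect_equal(mean_error(c(1, rep(0, 7)), rep(0, 8)), 1)
})

test_that("covariance error has the closed-form and invariance properties", {
  C <- random_spd(8, seed = 5)
  expect_equal(covariance_error(C, C), 0)
  expect_equal(covariance_error(C, exp(2) * C), sqrt(32), tolerance = 1e-8)
  expect_equal(covariance_error(C, exp(2) * C, squared = TRUE), 32,
               tolerance = 1e-6)
  C2 <- random_spd(8, seed = 6)
  base <- covariance_error(C, C2)
  set.seed(7)
  for (i in 1:20) {
    Mx <- matrix(rnorm(64), 8, 8)
    while (abs(det(Mx)) < 1e-3) Mx <- matrix(rnorm(64), 8, 8)
    expect_equal(covariance_error(Mx %*% C %*% t(Mx), Mx %*% C2 %*% t(Mx)),
                 base, tolerance = 1e-8)
  }
  # symmetry of the metric
  expect_equal(covariance_error(C2, C), base, tolerance = 1e-10)
})

make_scored_sample <- function(n, seed = 8) {
  set.seed(seed)
  obs <- matrix(rnorm(n * 4), n, 4)
  bins <- sample(seq(0, 315, by = 45), n, replace = TRUE)
  list(obs = obs, bins = bins)
}

test_that("self-prediction scores zero on all three metrics", {
  s <- make_scored_sample(800)
  sc <- score_null_predictions(s$obs, s$obs, s$bins, s$bins, h = 0.4)
  expect_equal(sc$hist_pct, 0)
  expect_equal(sc$mean_err, 0)
  expect_equal(sc$cov_err, 0)
})

test_that("metrics are invariant to a signed permutation of the null basis", {
  s <- make_scored_sample(600)
  pred <- make_scored_sample(600, seed = 9)
  sc <- score_null_predictions(s$obs, pred$obs, s$bins, pred$bins, h = 0.4)
  # signed permutation (the only basis freedom the SVD convention leaves)
  Q <- diag(c(1, -1, -1, 1))[, c(3, 1, 4, 2)]
  sc_q <- score_null_predictions(s$obs %*% Q, pred$obs %*% Q,
                                 s$bins, pred$bins, h = 0.4)
  expect_equal(sc_q$hist_pct, sc$hist_pct, tolerance = 1e-10)
  expect_equal(sc_q$mean_err, sc$mean_err, tolerance = 1e-10)
  expect_equal(sc_q$cov_err, sc$cov_err, tolerance = 1e-8)
  # mean and covariance errors survive any rotation of the null basis
  set.seed(10)
  Qr <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  sc_r <- score_null_predictions(s$obs %*% Qr, pred$obs %*% Qr,
                                 s$bins, pred$bins, h = 0.4)
  expect_equal(sc_r$mean_err, sc$mean_err, tolerance = 1e-10)
  expect_equal(sc_r$cov_err, sc$cov_err, tolerance = 1e-8)
})

test_that("error floors are reproducible, non-negative, and shrink with n", {
  s <- make_scored_sample(400, seed = 11)
  f1 <- error_floor(s$obs, s$bins, h = 0.4, n_reps = 20, seed = 2)
  f2 <- error_floor(s$obs, s$bins, h = 0.4, n_reps = 20, seed = 2)
  expect_equal(f1, f2)
  expect_true(all(f1$floor_mean >= 0))

  big <- make_scored_sample(4000, seed = 12)
  fb <- error_floor(big$obs, big$bins, h = 0.4, n_reps = 20, seed = 2)
  expect_lt(fb$floor_mean[1], f1$floor_mean[1])   # histogram floor
  expect_lt(fb$floor_mean[2], f1$floor_mean[2])   # mean floor
})

test_that("identical steps give a zero floor", {
  obs <- matrix(1.5, 200, 3)
  bins <- rep(c(0, 90), 100)
  fl <- error_floor(obs, bins, h = 0.5, n_reps = 5, seed = 1)
  expect_equal(fl$floor_mean[1], 0)
  expect_equal(fl$floor_mean[2], 0)
  expect_equal(fl$floor_mean[3], 0)
})

test_that("display PCA ordering is orthogonal and variance-sorted", {
  set.seed(13)
  X <- cbind(rnorm(500, sd = 5), rnorm(500, sd = 1), rnorm(500, sd = 0.2))
  ord <- display_pca_order(X)
  expect_equal(unname(crossprod(ord$rotation)), diag(3), tolerance = 1e-10)
  expect_equal(unname(ord$order[1]), 1)    # dominant direction first
  expect_true(all(diff(ord$var_explained) <= 1e-12))
  iso <- matrix(rnorm(3000), 1000, 3)
  vi <- display_pca_order(iso)$var_explained
  expect_lt(max(vi) - min(vi), 0.1)
})
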