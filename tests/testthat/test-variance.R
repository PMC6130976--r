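# Variance of activity in dimensions that switch potency, and the mean-shift
# comparison.

toy_mapping <- function(B, a = 0.8) bci_mapping(diag(a, 2), B, c(0, 0))

test_that("overlap subspace construction handles the canonical cases", {
  set.seed(1)
  m <- toy_mapping(matrix(rnorm(2 * 6), 2, 6))
  # a mapping's own row space has no overlap with its null space
  expect_error(overlap_subspace(m, m), "rank-0")

  # k = 4, disjoint potent axes: overlap is mapping-1's potent plane
  B1 <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  B2 <- rbind(c(0, 0, 1, 0), c(0, 0, 0, 1))
  S <- overlap_subspace(toy_mapping(B1), toy_mapping(B2))
  expect_equal(S$rank, 2)
  P <- S$basis %*% t(S$basis)
  expect_equal(P, diag(c(1, 1, 0, 0)), tolerance = 1e-10)

  # random pair: basis lies inside the null space of mapping 2
  m1 <- toy_mapping(matrix(rnorm(2 * 8), 2, 8))
  m2 <- toy_mapping(matrix(rnorm(2 * 8), 2, 8))
  S2 <- overlap_subspace(m1, m2)
  proj <- crossprod(S2$basis, m2$N %*% crossprod(m2$N, S2$basis))
  expect_equal(proj, diag(S2$rank), tolerance = 1e-8)
})

test_that("subspace variance matches closed forms", {
  set.seed(2)
  m1 <- toy_mapping(matrix(rnorm(2 * 6), 2, 6))
  m2 <- toy_mapping(matrix(rnorm(2 * 6), 2, 6))
  S <- overlap_subspace(m1, m2)
  Zc <- matrix(1.7, 50, 6)
  expect_equal(subspace_variance(Zc, S), 0)
  Zi <- matrix(rnorm(1e4 * 6), 1e4, 6)
  expect_equal(subspace_variance(Zi, S), S$rank, tolerance = 0.1)
  Z <- matrix(rnorm(300 * 6), 300, 6)
  expect_equal(subspace_variance(3 * Z, S), 9 * subspace_variance(Z, S),
               tolerance = 1e-10)
})

test_that("variance ratio is zero for identical sets and 2 for an e-scaling", {
  set.seed(3)
  m1 <- toy_mapping(matrix(rnorm(2 * 6), 2, 6))
  m2 <- toy_mapping(matrix(rnorm(2 * 6), 2, 6) + 0.1)
  S <- overlap_subspace(m1, m2)
  Z1 <- matrix(rnorm(2000 * 6), 2000, 6)
  vr0 <- variance_ratio(Z1, Z1, S, m2)
  expect_true(all(abs(vr0$directions$ratio) < 1e-12))
  expect_equal(vr0$average, 0)
  # scaling by e doubles the log ratio in every populated bin
  vre <- variance_ratio(Z1, exp(1) * Z1, S, m2)
  expect_true(all(abs(vre$directions$ratio - 2) < 0.15))
})

test_that("hypothesis-substituted ratios match a direct re-computation", {
  ctx <- small_context("coupled")
  s <- small_session("coupled")
  ps <- run_hypothesis(ctx, "uncontrolled_empirical",
                       cfg = hypothesis_config(seed = 2))
  S <- overlap_subspace(s$mappings[[1]], ctx$map_eval)
  Z1 <- ctx$Z[ctx$idx_src, ]
  Z2h <- recombine_predictions(ps, ctx)
  vr <- variance_ratio(Z1, Z2h, S, ctx$map_eval)

  # independent re-computation from first principles
  ang <- function(Z) {
    v <- Z %*% t(ctx$map_eval$B) +
      matrix(ctx$map_eval$c, nrow(Z), 2, byrow = TRUE)
    (floor(((atan2(v[, 2], v[, 1]) * 180 / pi) %% 360 + 22.5) / 45) * 45) %% 360
  }
  b1 <- ang(Z1); b2 <- ang(Z2h)
  for (r in seq_len(nrow(vr$directions))) {
    ct <- vr$directions$direction[r]
    t1 <- sum(diag(cov(Z1[b1 == ct, ] %*% S$basis)))
    t2 <- sum(diag(cov(Z2h[b2 == ct, ] %*% S$basis)))
    expect_equal(vr$directions$ratio[r], log(t2 / t1), tolerance = 1e-10)
  }
})

test_that("all outputs are invariant to the basis freedom in S", {
  set.seed(4)
  m1 <- toy_mapping(matrix(rnorm(2 * 7), 2, 7))
  m2 <- toy_mapping(matrix(rnorm(2 * 7), 2, 7))
  S <- overlap_subspace(m1, m2)
  Z1 <- matrix(rnorm(1500 * 7), 1500, 7)
  Z2 <- matrix(rnorm(1200 * 7), 1200, 7) * 1.3
  base <- variance_ratio(Z1, Z2, S, m2)
  for (i in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(S$rank^2), S$rank, S$rank)))
    S_rot <- S; S_rot$basis <- S$basis %*% Q
    rot <- variance_ratio(Z1, Z2, S_rot, m2)
    expect_equal(rot$directions$ratio, base$directions$ratio,
                 tolerance = 1e-10)
  }
})

test_that("reverse-direction analysis equals the explicitly swapped one", {
  set.seed(5)
  m1 <- toy_mapping(matrix(rnorm(2 * 6), 2, 6))
  m2 <- toy_mapping(matrix(rnorm(2 * 6), 2, 6))
  Z1 <- matrix(rnorm(900 * 6), 900, 6)
  Z2 <- matrix(rnorm(900 * 6), 900, 6)
  # swapping mapping roles: overlap of potent-under-2 with null-under-1
  S_rev <- overlap_subspace(m2, m1)
  vr_rev <- variance_ratio(Z2, Z1, S_rev, m1)
  P <- m1$N %*% crossprod(m1$N, m2$R)
  sv <- svd(P)
  S_manual <- structure(list(basis = sv$u[, 1:2], rank = 2,
                             singular_values = sv$d),
                        class = "subspace_basis")
  vr_manual <- variance_ratio(Z2, Z1, S_manual, m1)
  expect_equal(vr_rev$directions$ratio, vr_manual$directions$ratio,
               tolerance = 1e-10)
})

test_that("mean-shift analysis matches the signed-rank enumeration oracle", {
  set.seed(6)
  mu_min <- matrix(rnorm(8 * 4), 8, 4)
  mu_fd <- matrix(rnorm(8 * 4), 8, 4)
  # observed identical to fixed-distribution: all paired differences zero
  res0 <- mean_shift_analysis(mu_fd, mu_fd, mu_min)
  expect_true(all(res0$directions$dist_obs_min == res0$directions$dist_fd_min))
  expect_equal(res0$p_value, 1)

  # observed placed exactly at the minimal means: strongest possible shift
  res1 <- mean_shift_analysis(mu_min, mu_fd, mu_min)
  expect_true(all(res1$directions$dist_obs_min == 0))
  expect_lt(res1$p_value, 0.05)

  # 3-direction toy: enumerate all sign assignments of the exact test
  d_obs <- c(1.0, 2.0, 0.5); d_fd <- c(1.5, 2.6, 1.4)
  mu_obs3 <- cbind(d_obs, 0); mu_fd3 <- cbind(d_fd, 0)
  mu_min3 <- matrix(0, 3, 2)
  res3 <- mean_shift_analysis(mu_obs3, mu_fd3, mu_min3)
  diffs <- d_obs - d_fd
  W <- sum(rank(abs(diffs))[diffs > 0])
  # null distribution of the positive-rank sum over all 2^3 sign patterns
  ranks <- rank(abs(diffs))
  null_W <- sapply(0:7, function(m) sum(ranks[bitwAnd(m, 2^(0:2)) > 0]))
  p_oracle <- mean(null_W <= W)
  expect_equal(res3$p_value, p_oracle, tolerance = 1e-10)
})
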