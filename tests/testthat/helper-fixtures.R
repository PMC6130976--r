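# Shared fixtures, built in code and cached for the test run.

fixture_env <- new.env(parent = emptyenv())

# A small but complete closed-loop session (any world), cached per world.
small_config <- function(world, seed = 42L) {
  sim_config(n_units = 36L, n_factors = 6L, n_trials_map1 = 60L,
             n_trials_map2 = 120L, burn_in = 30L, n_calibration = 600L,
             library_size = 1500L, world = world, seed = seed)
}

small_selection <- function() {
  selection_config(boxcar = 40L, min_block = 40L, join_gap = 5L)
}

small_session <- function(world = "coupled") {
  key <- paste0("session_", world)
  if (is.null(fixture_env[[key]])) {
    cfg <- small_config(world)
    gt <- make_ground_truth(cfg)
    fixture_env[[key]] <- simulate_session(gt, cfg)
  }
  fixture_env[[key]]
}

small_context <- function(world = "coupled", direction = "forward") {
  key <- paste0("context_", world, "_", direction)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- prediction_context(small_session(world), direction,
                                             sel = small_selection())
  }
  fixture_env[[key]]
}

# Hand-built prediction context with exactly known ingredients: orthonormal
# loading columns (so the factor map is transparent), an identity-like
# readout, and candidate/evaluation activity supplied by the caller.
toy_context <- function(q = 12L, k = 4L, n_eval = 20L, n_src = 50L,
                        seed = 99L, umax_scale = 50) {
  set.seed(seed)
  U <- qr.Q(qr(matrix(rnorm(q * k), q, k)))
  S <- seq(2, 1, length.out = k)
  L <- U %*% diag(S, k)
  d <- runif(q, 8, 12)
  fa <- structure(list(L = L, psi = rep(1, q), d = d,
                       orth_U = U, orth_S = S, orth_V = diag(k),
                       k = k, n_obs = 1000L, loglik = 0, converged = TRUE,
                       n_iter = 1L), class = "fa_model")
  B <- matrix(rnorm(2 * k), 2, k)
  m <- bci_mapping(diag(0.5, 2), B, c(0.1, -0.2))
  Z_all <- matrix(rnorm((n_eval + n_src) * k), n_eval + n_src, k)
  idx_eval <- seq_len(n_eval)
  idx_src <- n_eval + seq_len(n_src)
  sp <- split_activity(Z_all[idx_eval, , drop = FALSE], m)
  v_eval <- matrix(rnorm(n_eval * 2), n_eval, 2)
  structure(list(
    fa = fa, map_eval = m, Z = Z_all, idx_eval = idx_eval, idx_src = idx_src,
    z_r_eval = sp$z_r, z_n_obs = sp$z_n,
    v_eval = v_eval, v_prev_eval = matrix(0, n_eval, 2),
    theta_eval = runif(n_eval, 0, 360), theta_src = runif(n_src, 0, 360),
    v_src = matrix(rnorm(n_src * 2), n_src, 2),
    bounds = structure(rep(umax_scale, q), class = "physiological_bounds"),
    direction = "forward", block = NULL
  ), class = "prediction_context")
}

# Moore-Penrose pseudoinverse via SVD (independent of any package routine)
pinv <- function(A, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d)
  sv$v[, keep, drop = FALSE] %*% diag(1 / sv$d[keep], sum(keep)) %*%
    t(sv$u[, keep, drop = FALSE])
}

random_spd <- function(p, seed = 1L) {
  set.seed(seed)
  G <- matrix(rnorm(p * p), p, p)
  G %*% t(G) + diag(p)
}
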