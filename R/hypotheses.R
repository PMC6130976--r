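# The six predictors of output-null activity, with the shared physiological
# plausibility rejection scheme.

#' Hypothesis configuration
#'
#' @param max_attempts Resampling attempts before a time step is skipped.
#' @param wedge_halfwidth Half-width (degrees) of the cursor-target-angle
#'   wedge used by the Persistent Strategy hypothesis.
#' @param K Number of nearest neighbours the Fixed Distribution hypothesis
#'   samples among (K = 1 reproduces the deterministic nearest-neighbour
#'   form).
#' @param norm Objective for the Minimal Firing program: `"l2"` or `"l1"`.
#' @param poisson Whether the Minimal Firing / Minimal Deviation predictions
#'   incorporate Poisson spiking variability (TRUE in the full procedure;
#'   FALSE yields the noiseless optima, used for diagnostics).
#' @param seed Integer seed for all stochastic predictors.
#' @return A list of class `hypothesis_config`.
#' @export
hypothesis_config <- function(max_attempts = 100L, wedge_halfwidth = 22.5,
                              K = 1L, norm = c("l2", "l1"), poisson = TRUE,
                              seed = 1L) {
  norm <- match.arg(norm)
  stopifnot(max_attempts >= 1L, K >= 1L, wedge_halfwidth > 0)
  structure(list(max_attempts = as.integer(max_attempts),
                 wedge_halfwidth = wedge_halfwidth, K = as.integer(K),
                 norm = norm, poisson = isTRUE(poisson),
                 seed = as.integer(seed)),
            class = "hypothesis_config")
}

#' Hypothesis identifiers
#' @export
hypothesis_names <- function() {
  c("minimal_firing", "minimal_deviation", "uncontrolled_uniform",
    "uncontrolled_empirical", "persistent_strategy", "fixed_distribution")
}

#' Per-unit physiological bounds
#'
#' The maximum spike count per bin observed for each unit during trials under
#' the first BCI mapping; predictions whose implied counts exceed these
#' bounds (or fall below zero) are rejected.
#'
#' @param session A `bci_session`.
#' @return Numeric vector of per-unit maxima, class `physiological_bounds`.
#' @export
physiological_bounds <- function(session) {
  m1_steps <- session$steps$trial %in% which(session$trials$mapping == 1L)
  umax <- apply(session$counts[m1_steps, , drop = FALSE], 2L, max)
  structure(pmax(umax, 1), class = "physiological_bounds")
}

#' Physiological plausibility of a predicted output-null pattern
#'
#' Reconstructs the factor pattern \eqn{z = N z^n + R z^r}, maps it to unit
#' space through the generative relation \eqn{\hat u = U \tilde z + d} (equal
#' to \eqn{L z_{raw} + d} in the orthonormalized convention), and tests
#' \eqn{0 \le \hat u \le u_{max}} elementwise.
#'
#' @param z_n Null vector (length k-2).
#' @param z_r Potent vector (length 2).
#' @param m A [bci_mapping()].
#' @param fa An [fit_fa()] model.
#' @param bounds A [physiological_bounds()] vector.
#' @param tol Numerical slack on the bounds.
#' @return TRUE/FALSE.
#' @export
check_plausible <- function(z_n, z_r, m, fa, bounds, tol = 1e-9) {
  z <- drop(m$N %*% z_n + m$R %*% z_r)
  u <- drop(fa$orth_U %*% z + fa$d)
  all(u >= -tol) && all(u <= unclass(bounds) + tol)
}

#' Build the shared inputs of the output-null predictors
#'
#' Collects, for one prediction direction, everything the six hypotheses
#' need: the factor trajectories, the evaluation-side mapping (whose null
#' space is predicted), the candidate time steps recorded under the other
#' mapping, observed potent components and kinematics, and the physiological
#' bounds.
#'
#' @param session A `bci_session`.
#' @param direction `"forward"` predicts second-mapping output-null activity
#'   from first-mapping candidates; `"reverse"` swaps the mapping roles.
#' @param block A [select_stable_block()] result for the second-mapping
#'   trials, or `NULL` to compute it from the session's trial table.
#' @param sel A [selection_config()].
#' @return A list of class `prediction_context`.
#' @export
prediction_context <- function(session, direction = c("forward", "reverse"),
                               block = NULL, sel = selection_config()) {
  direction <- match.arg(direction)
  if (is.null(block)) {
    tr2 <- session$trials[session$trials$mapping == 2L, ]
    block <- select_stable_block(tr2$acq_time, tr2$success, sel)
  }
  if (!block$found) stop("no stable block: ", block$reason)

  mask1 <- filter_timesteps(session, mapping = 1L, block = NULL, cfg = sel)
  mask2 <- filter_timesteps(session, mapping = 2L, block = block, cfg = sel)
  Z <- counts_to_factors(session$counts, session$fa)

  # Candidate pools are all time steps recorded under proficient control of
  # the source mapping (every first-mapping step; stable-block steps for the
  # second mapping); the evaluation side carries the analysis filters
  # (success, freeze, distance band, stable block).
  st <- session$steps
  src1 <- st$mapping == 1L
  tr2 <- which(session$trials$mapping == 2L)
  in_block2 <- rep(FALSE, nrow(session$trials))
  in_block2[tr2[seq(block$start, block$end)]] <- TRUE
  src2 <- in_block2[st$trial]

  if (direction == "forward") {
    map_eval <- session$mappings[[2L]]
    idx_eval <- which(mask2); idx_src <- which(src1)
  } else {
    map_eval <- session$mappings[[1L]]
    idx_eval <- which(mask1); idx_src <- which(src2)
  }
  if (length(idx_src) == 0L) stop("no candidate time steps")

  st <- session$steps
  sp <- split_activity(Z[idx_eval, , drop = FALSE], map_eval)
  structure(list(
    fa = session$fa, map_eval = map_eval,
    Z = Z, idx_eval = idx_eval, idx_src = idx_src,
    counts = session$counts,
    z_r_eval = sp$z_r, z_n_obs = sp$z_n,
    v_eval = cbind(st$v_x, st$v_y)[idx_eval, , drop = FALSE],
    v_prev_eval = cbind(st$v_prev_x, st$v_prev_y)[idx_eval, , drop = FALSE],
    theta_eval = st$theta[idx_eval], theta_src = st$theta[idx_src],
    v_src = cbind(st$v_x, st$v_y)[idx_src, , drop = FALSE],
    bounds = physiological_bounds(session),
    direction = direction, block = block
  ), class = "prediction_context")
}

#' Run one output-null hypothesis over a session
#'
#' Applies the chosen predictor at every included time step of the evaluation
#' mapping, with the shared plausibility rejection scheme (at most
#' `cfg$max_attempts` resampling attempts per step, after which the step is
#' skipped).
#'
#' @param session A `bci_session`, or a prebuilt [prediction_context()].
#' @param hypothesis One of [hypothesis_names()].
#' @param direction `"forward"` or `"reverse"` (ignored when a context is
#'   supplied).
#' @param cfg A [hypothesis_config()].
#' @param ... Passed to [prediction_context()] when `session` is a session.
#' @return A `prediction_set`: per-step predictions (matrix `pred`, one row
#'   per evaluation step, `NA` rows where skipped), a `steps` tibble with
#'   time index, skip flags and attempt counts, and the skip fraction.
#' @export
run_hypothesis <- function(session, hypothesis, direction = "forward",
                           cfg = hypothesis_config(), ...) {
  hypothesis <- match.arg(hypothesis, hypothesis_names())
  ctx <- if (inherits(session, "prediction_context")) session
         else prediction_context(session, direction, ...)
  set.seed(derive_seed(cfg$seed, match(hypothesis, hypothesis_names())))

  res <- switch(hypothesis,
    minimal_firing = predict_minimal_firing(ctx, cfg),
    minimal_deviation = predict_minimal_deviation(ctx, cfg),
    uncontrolled_uniform = predict_uncontrolled_uniform(ctx, cfg),
    uncontrolled_empirical = predict_uncontrolled_empirical(ctx, cfg),
    persistent_strategy = predict_persistent_strategy(ctx, cfg),
    fixed_distribution = predict_fixed_distribution(ctx, cfg)
  )

  skipped <- res$skipped
  structure(list(
    hypothesis = hypothesis, direction = ctx$direction,
    pred = res$pred,
    steps = tibble::tibble(t = ctx$idx_eval, skipped = skipped,
                           attempts = res$attempts),
    skip_fraction = mean(skipped),
    seed = cfg$seed
  ), class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("Output-null predictions [", x$hypothesis, ", ", x$direction, "]: ",
      nrow(x$pred), " steps, ",
      sprintf("%.2f%%", 100 * x$skip_fraction), " skipped\n", sep = "")
  invisible(x)
}

#' @export
tidy.prediction_set <- function(x, ...) {
  p <- as_tibble(as.data.frame(x$pred), .name_repair = ~ paste0("null_dim", seq_along(.x)))
  dplyr::bind_cols(x$steps, p, hypothesis = x$hypothesis)
}

# ---- shared machinery ------------------------------------------------------

# Plausibility of continuous reconstructions, vectorized over steps.
# Zn: n x (k-2), Zr: n x 2 -> logical n
plausible_rows <- function(Zn, Zr, ctx, tol = 1e-9) {
  Uh <- ctx$fa$orth_U
  U_n <- Uh %*% ctx$map_eval$N
  U_r <- Uh %*% ctx$map_eval$R
  Uu <- Zn %*% t(U_n) + Zr %*% t(U_r)
  Uu <- sweep(Uu, 2L, ctx$fa$d, `+`)
  ok_lo <- rowSums(Uu < -tol) == 0L
  ok_hi <- rowSums(sweep(Uu, 2L, unclass(ctx$bounds) + tol, `>`)) == 0L
  ok_lo & ok_hi
}

# Generic rejection-sampling driver: draw(idx) proposes an n_idx x (k-2)
# matrix for the still-unresolved steps; rows passing the continuous
# plausibility check are accepted.
sample_until_plausible <- function(ctx, cfg, draw) {
  n <- nrow(ctx$z_r_eval)
  p <- ncol(ctx$map_eval$N)
  pred <- matrix(NA_real_, n, p)
  attempts <- integer(n)
  open <- seq_len(n)
  for (a in seq_len(cfg$max_attempts)) {
    if (length(open) == 0L) break
    prop <- draw(open)
    attempts[open] <- a
    ok <- plausible_rows(prop, ctx$z_r_eval[open, , drop = FALSE], ctx)
    pred[open[ok], ] <- prop[ok, , drop = FALSE]
    open <- open[!ok]
  }
  list(pred = pred, attempts = attempts,
       skipped = seq_len(n) %in% open)
}

# ---- Minimal Firing --------------------------------------------------------

predict_minimal_firing <- function(ctx, cfg) {
  fa <- ctx$fa
  M <- factor_map_matrix(fa)             # k x q, f(u) = M (u - d)
  G <- ctx$map_eval$B %*% M              # 2 x q
  m <- ctx$map_eval
  umax <- unclass(ctx$bounds)
  n <- length(ctx$idx_eval)
  p <- ncol(m$N)
  NM <- t(m$N) %*% M                     # (k-2) x q

  rhs_all <- ctx$v_eval - ctx$v_prev_eval %*% t(m$A) -
    matrix(m$c, n, 2L, byrow = TRUE) + matrix(drop(G %*% fa$d), n, 2L, byrow = TRUE)

  pred <- matrix(NA_real_, n, p)
  attempts <- integer(n)
  skipped <- logical(n)
  for (i in seq_len(n)) {
    sol <- min_norm_program(G, rhs_all[i, ], lower = 0, upper = umax,
                            norm = cfg$norm)
    if (!sol$feasible) { skipped[i] <- TRUE; next }
    if (!cfg$poisson) {
      pred[i, ] <- drop(NM %*% (sol$u - fa$d))
      attempts[i] <- 1L
      next
    }
    ok <- FALSE
    for (a in seq_len(cfg$max_attempts)) {
      u2 <- rpois(length(sol$u), sol$u)
      if (all(u2 <= umax)) {            # counts are non-negative integers
        pred[i, ] <- drop(NM %*% (u2 - fa$d))
        attempts[i] <- a
        ok <- TRUE
        break
      }
    }
    if (!ok) skipped[i] <- TRUE
  }
  list(pred = pred, attempts = attempts, skipped = skipped)
}

# ---- Minimal Deviation -----------------------------------------------------

#' Fit the Minimal Deviation baseline pattern
#'
#' Estimates \eqn{\eta = N(\frac{1}{8}\sum_i \mu^n_i)} where \eqn{\mu^n_i} is
#' the mean output-null activity (null space of the evaluation mapping) of
#' the candidate steps falling in the i-th cursor-direction bin, directions
#' taken from the candidates' own recorded cursor velocities. Empty direction
#' bins are omitted from the average with a warning.
#'
#' @param Z_src Candidate factor activity (n x k).
#' @param v_src Their recorded cursor velocities (n x 2).
#' @param m_eval The mapping whose null space is being predicted.
#' @return A list with the k-vector `eta` and its null coordinates
#'   `null_mean`.
#' @export
fit_eta <- function(Z_src, v_src, m_eval) {
  bins <- bin_timesteps(v_src)
  Zn <- Z_src %*% m_eval$N
  centers <- seq(0, 315, by = 45)
  mu <- vapply(centers, function(ct) {
    idx <- which(!is.na(bins) & bins == ct)
    if (length(idx) == 0L) rep(NA_real_, ncol(Zn))
    else colMeans(Zn[idx, , drop = FALSE])
  }, numeric(ncol(Zn)))
  present <- colSums(is.na(mu)) == 0L
  if (!all(present)) warning("empty cursor-direction bin(s) omitted from eta")
  null_mean <- rowMeans(mu[, present, drop = FALSE])
  list(eta = drop(m_eval$N %*% null_mean), null_mean = null_mean)
}

predict_minimal_deviation <- function(ctx, cfg) {
  fa <- ctx$fa
  m <- ctx$map_eval
  eta_fit <- fit_eta(ctx$Z[ctx$idx_src, , drop = FALSE], ctx$v_src, m)
  n <- length(ctx$idx_eval)
  p <- ncol(m$N)
  if (!cfg$poisson) {
    pred <- matrix(eta_fit$null_mean, n, p, byrow = TRUE)
    return(list(pred = pred, attempts = rep(1L, n), skipped = logical(n)))
  }
  M <- factor_map_matrix(fa)
  NM <- t(m$N) %*% M
  umax <- unclass(ctx$bounds)
  # per-step rates: u = U (N eta_n + R z_r) + d, clipped at zero
  Zhat <- matrix(eta_fit$null_mean, n, p, byrow = TRUE) %*% t(m$N) +
    ctx$z_r_eval %*% t(m$R)
  rates <- pmax(sweep(Zhat %*% t(fa$orth_U), 2L, fa$d, `+`), 0)

  pred <- matrix(NA_real_, n, p)
  attempts <- integer(n)
  open <- seq_len(n)
  q <- length(fa$d)
  for (a in seq_len(cfg$max_attempts)) {
    if (length(open) == 0L) break
    draws <- matrix(rpois(length(open) * q, t(rates[open, , drop = FALSE])),
                    nrow = q)
    ok <- colSums(draws > umax) == 0L
    attempts[open] <- a
    acc <- open[ok]
    if (length(acc)) {
      pred[acc, ] <- t(NM %*% (draws[, ok, drop = FALSE] - fa$d))
    }
    open <- open[!ok]
  }
  list(pred = pred, attempts = attempts, skipped = seq_len(n) %in% open)
}

# ---- Uncontrolled-uniform --------------------------------------------------

predict_uncontrolled_uniform <- function(ctx, cfg) {
  Zn_src <- ctx$Z[ctx$idx_src, , drop = FALSE] %*% ctx$map_eval$N
  lo <- apply(Zn_src, 2L, min)
  hi <- apply(Zn_src, 2L, max)
  p <- length(lo)
  draw <- function(open) {
    matrix(runif(length(open) * p, rep(lo, each = length(open)),
                 rep(hi, each = length(open))), length(open), p)
  }
  sample_until_plausible(ctx, cfg, draw)
}

# ---- Uncontrolled-empirical ------------------------------------------------

predict_uncontrolled_empirical <- function(ctx, cfg) {
  Zn_src <- ctx$Z[ctx$idx_src, , drop = FALSE] %*% ctx$map_eval$N
  draw <- function(open) {
    Zn_src[sample.int(nrow(Zn_src), length(open), replace = TRUE), ,
           drop = FALSE]
  }
  sample_until_plausible(ctx, cfg, draw)
}

# ---- Persistent Strategy ---------------------------------------------------

# circular distance in degrees, in [0, 180]
circular_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

predict_persistent_strategy <- function(ctx, cfg) {
  Zn_src <- ctx$Z[ctx$idx_src, , drop = FALSE] %*% ctx$map_eval$N
  th_src <- ctx$theta_src
  usable <- !is.na(th_src)
  Zn_src <- Zn_src[usable, , drop = FALSE]
  th_src <- th_src[usable]
  ord <- order(th_src)
  th_sorted <- th_src[ord]
  Zn_sorted <- Zn_src[ord, , drop = FALSE]
  n_src <- length(th_sorted)

  th_eval <- ctx$theta_eval
  n <- length(th_eval)
  hw <- cfg$wedge_halfwidth

  # contiguous index ranges in the sorted angles for the wedge theta +/- hw,
  # handling wrap-around at 0/360
  sample_one_range <- function(lo, hi, m) {
    # positions in [lo, hi) within th_sorted; returns m sampled positions
    a <- findInterval(lo, th_sorted, left.open = TRUE) + 1L
    b <- findInterval(hi, th_sorted)
    if (b < a) integer(0) else a + sample.int(b - a + 1L, m, replace = TRUE) - 1L
  }
  wedge_positions <- function(th) {
    lo <- (th - hw) %% 360
    hi <- (th + hw) %% 360
    if (lo <= hi) {
      a <- findInterval(lo, th_sorted, left.open = TRUE) + 1L
      b <- findInterval(hi, th_sorted)
      if (b < a) integer(0) else seq.int(a, b)
    } else {
      a1 <- findInterval(lo, th_sorted, left.open = TRUE) + 1L
      part1 <- if (a1 <= n_src) seq.int(a1, n_src) else integer(0)
      b2 <- findInterval(hi, th_sorted)
      part2 <- if (b2 >= 1L) seq.int(1L, b2) else integer(0)
      c(part1, part2)
    }
  }
  wedges <- lapply(th_eval, function(th) {
    if (is.na(th)) integer(0) else wedge_positions(th)
  })
  empty <- lengths(wedges) == 0L

  draw <- function(open) {
    pos <- vapply(open, function(i) {
      w <- wedges[[i]]
      w[sample.int(length(w), 1L)]
    }, integer(1))
    Zn_sorted[pos, , drop = FALSE]
  }

  # steps with an empty wedge are skipped outright
  n_dim <- ncol(ctx$map_eval$N)
  if (all(empty)) {
    return(list(pred = matrix(NA_real_, n, n_dim), attempts = integer(n),
                skipped = rep(TRUE, n)))
  }
  ctx_sub <- ctx
  ctx_sub$z_r_eval <- ctx$z_r_eval[!empty, , drop = FALSE]
  wedges_sub <- wedges[!empty]
  draw_sub <- function(open) {
    pos <- vapply(open, function(i) {
      w <- wedges_sub[[i]]
      w[sample.int(length(w), 1L)]
    }, integer(1))
    Zn_sorted[pos, , drop = FALSE]
  }
  res <- sample_until_plausible(ctx_sub, cfg, draw_sub)

  pred <- matrix(NA_real_, n, n_dim)
  attempts <- integer(n)
  skipped <- rep(TRUE, n)
  pred[!empty, ] <- res$pred
  attempts[!empty] <- res$attempts
  skipped[!empty] <- res$skipped
  list(pred = pred, attempts = attempts, skipped = skipped)
}

# ---- Fixed Distribution ----------------------------------------------------

predict_fixed_distribution <- function(ctx, cfg) {
  Z_src <- ctx$Z[ctx$idx_src, , drop = FALSE]
  m <- ctx$map_eval
  P_src <- Z_src %*% m$R                  # candidates' potent coords (n_src x 2)
  Zn_src <- Z_src %*% m$N
  P_eval <- ctx$z_r_eval
  n <- nrow(P_eval)
  n_src <- nrow(P_src)
  K <- min(cfg$K, n_src)

  src_sq <- rowSums(P_src^2)
  nn_of <- function(rows) {
    # exact scan, chunked; ties broken by lowest candidate index
    d2 <- matrix(rowSums(P_eval[rows, , drop = FALSE]^2), length(rows), n_src) +
      matrix(src_sq, length(rows), n_src, byrow = TRUE) -
      2 * P_eval[rows, , drop = FALSE] %*% t(P_src)
    if (K == 1L) {
      matrix(max.col(-d2, ties.method = "first"), ncol = 1L)
    } else {
      t(apply(d2, 1L, function(r) order(r)[seq_len(K)]))
    }
  }
  chunk <- 512L
  nn <- matrix(NA_integer_, n, K)
  for (s in seq(1L, n, by = chunk)) {
    rows <- s:min(s + chunk - 1L, n)
    nn[rows, ] <- nn_of(rows)
  }

  if (K == 1L) {
    pred <- Zn_src[nn[, 1L], , drop = FALSE]
    ok <- plausible_rows(pred, P_eval, ctx)
    pred[!ok, ] <- NA_real_
    return(list(pred = pred, attempts = rep(1L, n), skipped = !ok))
  }
  draw <- function(open) {
    pick <- nn[cbind(open, sample.int(K, length(open), replace = TRUE))]
    Zn_src[pick, , drop = FALSE]
  }
  sample_until_plausible(ctx, cfg, draw)
}
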