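# Closed-loop two-mapping center-out BCI session simulator with known
# ground-truth coupling between output-null and output-potent activity.

#' Simulation configuration
#'
#' Defaults mirror the experimental constants of the study design this
#' package analyzes: ~90 units driven by a 10-D intrinsic manifold, 45 ms
#' count bins, an 8-target center-out task at 85 mm with a 300 ms cursor
#' freeze and 7.5 s timeout, 300 trials under the first (intuitive) mapping
#' and 500 under the permuted second mapping with a 100-trial re-aiming
#' burn-in.
#'
#' @param n_units Number of recorded units.
#' @param n_factors Intrinsic-manifold dimensionality (k, >= 3).
#' @param bin_ms Count-bin duration (ms).
#' @param n_trials_map1,n_trials_map2 Trials under each mapping.
#' @param world Ground-truth rule coupling output-null to output-potent
#'   activity: `"coupled"` (fixed repertoire, null follows potent),
#'   `"independent"` (null drawn from a fixed distribution ignoring potent)
#'   or `"minimal"` (null minimizing the implied spike counts).
#' @param coupling_noise Null-space noise of the coupled rule, relative to
#'   the repertoire's null spread.
#' @param library_size Number of repertoire patterns.
#' @param library_sd Repertoire scatter around the tuning curve (raw factor
#'   units; tuning amplitudes are order 1).
#' @param target_distance Center-to-target distance (mm).
#' @param acquisition_radius Cursor-target distance (mm) counting as
#'   acquisition.
#' @param timeout_s Maximum cursor-control time per trial (s).
#' @param freeze_ms Cursor-freeze duration at trial start (ms); realized as
#'   whole bins (ceiling).
#' @param burn_in Second-mapping trials over which the subject's believed
#'   readout ramps from the first to the second mapping (the learning phase
#'   that trial selection discards).
#' @param n_calibration Calibration bins used to fit the factor model and the
#'   first mapping.
#' @param intended_speed Intended cursor speed (mm/s).
#' @param aim_noise_deg Initial exploratory aiming-noise sd (degrees) at the
#'   start of the second-mapping burn-in; decays linearly to
#'   `aim_noise_floor` across the burn-in block.
#' @param aim_noise_floor Residual aiming-noise sd (degrees) of proficient
#'   control.
#' @param smoothing Velocity-smoothing coefficient a (readout A = a I).
#' @param baseline_range Per-unit baseline count range per bin (uniform).
#' @param loading_scale Scale of the ground-truth loading entries.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_units = 90L, n_factors = 10L, bin_ms = 45,
                       n_trials_map1 = 300L, n_trials_map2 = 500L,
                       world = c("coupled", "independent", "minimal"),
                       coupling_noise = 0.5, library_size = 4000L,
                       library_sd = 0.4,
                       target_distance = 85, acquisition_radius = 15,
                       timeout_s = 7.5, freeze_ms = 300, burn_in = 100L,
                       n_calibration = 1500L, intended_speed = 60,
                       aim_noise_deg = 75, aim_noise_floor = 8,
                       smoothing = 0.8, baseline_range = c(1.2, 2.2),
                       loading_scale = 0.25, seed = 1L) {
  world <- match.arg(world)
  stopifnot(n_factors >= 3L, n_units > n_factors, bin_ms > 0, freeze_ms > 0,
            timeout_s > 0, target_distance > 0, acquisition_radius > 0,
            coupling_noise >= 0, smoothing >= 0, smoothing < 1)
  structure(list(n_units = as.integer(n_units),
                 n_factors = as.integer(n_factors),
                 bin_ms = bin_ms, bin_s = bin_ms / 1000,
                 n_trials_map1 = as.integer(n_trials_map1),
                 n_trials_map2 = as.integer(n_trials_map2),
                 world = world, coupling_noise = coupling_noise,
                 library_size = as.integer(library_size),
                 library_sd = library_sd,
                 target_distance = target_distance,
                 acquisition_radius = acquisition_radius,
                 timeout_s = timeout_s, freeze_ms = freeze_ms,
                 n_freeze = as.integer(ceiling(freeze_ms / bin_ms)),
                 max_ctrl_bins = as.integer(ceiling(timeout_s * 1000 / bin_ms)),
                 burn_in = as.integer(burn_in),
                 n_calibration = as.integer(n_calibration),
                 intended_speed = intended_speed,
                 aim_noise_deg = aim_noise_deg,
                 aim_noise_floor = aim_noise_floor, smoothing = smoothing,
                 baseline_range = baseline_range,
                 loading_scale = loading_scale, seed = as.integer(seed)),
            class = "sim_config")
}

# cosine-tuned repertoire curve in raw factor space: m_j(phi) = a_j cos(phi - psi_j)
tuning_curve <- function(phi, amps, phases) {
  outer(phi, seq_along(amps), function(p, j) amps[j] * cos(p - phases[j]))
}

#' Generate the ground-truth activity process
#'
#' Builds the true loading/noise/baseline of the units, a fixed cosine-tuned
#' activity repertoire (the "natural" population patterns, parameterized by
#' intended movement direction), and the world-specific coupling rule that
#' draws output-null activity given a required output-potent value. The rule
#' is identical under every mapping; in the coupled world it looks up the
#' repertoire pattern whose potent projection best matches the requirement
#' (a deterministic function of the potent value when `coupling_noise = 0`).
#'
#' @param config A [sim_config()].
#' @return A list of class `bci_ground_truth`; `$coupling_rule(potent, N, R,
#'   frame)` maps an n x 2 matrix of potent requirements to an n x (k-2)
#'   matrix of null draws, in the coordinates of the supplied null/row bases
#'   and generative frame (defaulting to the true-model frame).
#' @export
make_ground_truth <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  q <- config$n_units
  k <- config$n_factors

  # geometrically decaying factor strengths give a realistic, steeply
  # dropping shared-variance spectrum (top factors dominate)
  strengths <- 1.6 * (0.35 / 1.6)^((seq_len(k) - 1) / (k - 1))
  L <- matrix(rnorm(q * k), q, k) %*% diag(config$loading_scale * strengths, k)
  # baselines scale with each unit's modulation depth (strongly modulated
  # units fire more), keeping linear rates away from zero
  d <- runif(q, config$baseline_range[1L], config$baseline_range[2L]) +
    1.2 * sqrt(rowSums(L^2))
  psi <- d  # Poisson-matched noise variances for the generative model

  amps <- runif(k, 0.7, 1.3)
  phases <- runif(k, 0, 2 * pi)
  phi <- runif(config$library_size, 0, 2 * pi)
  lib_raw <- tuning_curve(phi, amps, phases) +
    matrix(rnorm(config$library_size * k, sd = config$library_sd),
           config$library_size, k)

  sv <- svd(L)
  frame_true <- list(
    U = sv$u, d = d,
    M = diag(sv$d, k) %*% t(sv$v) %*% woodbury_beta(L, psi),
    Z_lib = lib_raw %*% sv$v %*% diag(sv$d, k)
  )

  gt <- structure(list(
    true_loading = L, true_noise = psi, true_baseline = d,
    world = config$world, coupling_noise = config$coupling_noise,
    library_raw = lib_raw, library_phi = phi,
    tuning_amps = amps, tuning_phases = phases,
    frame = frame_true, k = k, q = q, seed = config$seed
  ), class = "bci_ground_truth")
  gt$coupling_rule <- function(potent, N, R, frame = gt$frame) {
    coupling_draw(gt$world, as.matrix(potent), N, R, frame, gt$coupling_noise)
  }
  gt
}

# beta = L'(LL'+Psi)^-1 via Woodbury (shared with the FA module's convention)
woodbury_beta <- function(L, psi) {
  Lp <- L / psi
  solve(diag(ncol(L)) + crossprod(L, Lp), t(Lp))
}

# World-specific null draw given required potent values (rows of `potent`),
# in the basis (N, R) and generative frame supplied.
coupling_draw <- function(world, potent, N, R, frame, coupling_noise) {
  n <- nrow(potent)
  p <- ncol(N)
  Zn_lib <- frame$Z_lib %*% N
  if (world == "independent") {
    mu <- colMeans(Zn_lib)
    sdv <- apply(Zn_lib, 2L, sd)
    return(matrix(rnorm(n * p, mean = rep(mu, each = n),
                        sd = rep(sdv, each = n)), n, p))
  }
  if (world == "coupled") {
    P_lib <- frame$Z_lib %*% R
    sq <- rowSums(P_lib^2)
    idx <- integer(n)
    for (i in seq_len(n)) {
      idx[i] <- which.min(sq - 2 * (P_lib[, 1L] * potent[i, 1L] +
                                      P_lib[, 2L] * potent[i, 2L]))
    }
    base <- Zn_lib[idx, , drop = FALSE]
    if (coupling_noise > 0) {
      sdn <- coupling_noise * mean(apply(Zn_lib, 2L, sd))
      base <- base + matrix(rnorm(n * p, sd = sdn), n, p)
    }
    return(base)
  }
  # minimal: null component of the count vector of smallest norm achieving
  # the required potent value
  G <- crossprod(R, frame$M)              # 2 x q
  NM <- crossprod(N, frame$M)
  Gd <- drop(G %*% frame$d)
  out <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) {
    sol <- min_norm_program(G, potent[i, ] + Gd, lower = 0, upper = Inf)
    out[i, ] <- drop(NM %*% (sol$u - frame$d))
  }
  out
}

#' Simulate a closed-loop two-mapping BCI session
#'
#' Runs a calibration block (tuned repertoire activity, Poisson counts), fits
#' the factor-analysis model to it, calibrates the first velocity mapping by
#' least squares against the intended calibration velocities, permutes it
#' within the manifold to create the second mapping, and then simulates every
#' trial in closed loop: at each 45 ms step the subject aims at the target
#' through the current mapping (re-aiming is instantaneous, but exploratory
#' aiming noise decays across the second-mapping burn-in block, producing a
#' monkey-like learning curve), produces factor activity whose
#' potent component achieves the intended velocity in expectation (the
#' subject compensates the posterior shrinkage of the decode chain) and whose
#' null component follows the world's coupling rule, and emits Poisson spike
#' counts around the clipped implied rates. The cursor is driven by decoding
#' the *emitted* counts, so the recorded velocities are exactly reproduced by
#' the readout applied to the recorded factor trajectories.
#'
#' @param gt A [make_ground_truth()] object.
#' @param config The same [sim_config()] used to build `gt`.
#' @return A list of class `bci_session`: integer `counts` (bins x units),
#'   `trials` and `steps` tibbles, the two `mappings`, the fitted `fa` model,
#'   the generative `frame`, the calibration counts, and the rate-clipping
#'   fraction.
#' @export
simulate_session <- function(gt, config) {
  set.seed(derive_seed(config$seed, 2L))
  q <- config$n_units
  k <- config$n_factors
  bin_s <- config$bin_s

  # ---- calibration block ---------------------------------------------------
  n_cal <- config$n_calibration
  phi_cal <- rep(seq(0, 2 * pi, length.out = 9L)[1:8], length.out = n_cal) +
    rnorm(n_cal, sd = 0.15)
  z_raw_cal <- tuning_curve(phi_cal, gt$tuning_amps, gt$tuning_phases) +
    matrix(rnorm(n_cal * k, sd = config$library_sd), n_cal, k)
  rates_cal <- pmax(z_raw_cal %*% t(gt$true_loading) +
                      matrix(gt$true_baseline, n_cal, q, byrow = TRUE), 0)
  counts_cal <- matrix(rpois(n_cal * q, rates_cal), n_cal, q)

  fa <- fit_fa(counts_cal, k = k, seed = derive_seed(config$seed, 3L))

  # ---- first mapping from calibration regression ---------------------------
  a <- config$smoothing
  A <- diag(a, 2L)
  Zc <- counts_to_factors(counts_cal, fa)
  v_lab <- config$intended_speed * cbind(cos(phi_cal), sin(phi_cal))
  X <- cbind(1, Zc)
  coef <- solve(crossprod(X), crossprod(X, (1 - a) * v_lab))
  m1 <- bci_mapping(A, t(coef[-1L, , drop = FALSE]), coef[1L, ])

  # ---- generative frame in the fitted factor space -------------------------
  M <- factor_map_matrix(fa)
  rates_lib <- pmax(gt$library_raw %*% t(gt$true_loading) +
                      matrix(gt$true_baseline, nrow(gt$library_raw), q,
                             byrow = TRUE), 0)
  frame <- list(U = fa$orth_U, d = fa$d, M = M,
                Z_lib = sweep(rates_lib, 2L, fa$d) %*% t(M))

  W <- M %*% fa$orth_U                   # learned loop gain (posterior shrinkage)

  # ---- second mapping: a learnable but substantial permutation -------------
  # Like a real experimental protocol, screen candidate permutations: the perturbed
  # mapping must be learnable (worst-direction steady-state speed afforded by
  # the repertoire clears 40% of the intended speed) yet a real perturbation
  # (it rotates the decoded directions of the repertoire patterns). Among
  # learnable candidates the most strongly rotating one is kept; if none is
  # learnable, the fastest candidate is used.
  set.seed(derive_seed(config$seed, 4L))
  worst_speed <- function(m) {
    P_lib <- frame$Z_lib %*% m$R
    E <- m$B %*% W %*% m$R %*% chol(cov(P_lib))
    min(svd(E)$d) * sqrt(stats::qchisq(0.95, df = 2L)) / (1 - a)
  }
  dir1 <- atan2(frame$Z_lib %*% t(m1$B[2L, , drop = FALSE]),
                frame$Z_lib %*% t(m1$B[1L, , drop = FALSE]))
  dir_change <- function(m) {
    d2 <- atan2(frame$Z_lib %*% t(m$B[2L, , drop = FALSE]),
                frame$Z_lib %*% t(m$B[1L, , drop = FALSE]))
    stats::median(abs(((dir1 - d2) * 180 / pi + 180) %% 360 - 180))
  }
  best <- NULL; best_score <- -Inf; fastest <- NULL; fastest_speed <- -Inf
  for (try in seq_len(200L)) {
    perm <- sample.int(k)
    if (all(perm == seq_len(k))) next
    cand <- permute_mapping(m1, perm)
    ws <- worst_speed(cand)
    if (ws > fastest_speed) { fastest <- cand; fastest_speed <- ws }
    if (ws >= 0.4 * config$intended_speed) {
      dc <- dir_change(cand)
      if (dc > best_score) { best <- cand; best_score <- dc }
    }
  }
  m2 <- if (!is.null(best)) best else fastest

  # Controller pieces for a believed readout. The subject cannot produce
  # potent values outside its natural repertoire: requirements are clamped to
  # the repertoire's potent support (Mahalanobis ellipse), so movements along
  # poorly covered readout directions are slower rather than extrapolated.
  make_ctl <- function(m) {
    BW <- m$B %*% W
    P_lib <- frame$Z_lib %*% m$R
    mu_p <- colMeans(P_lib)
    Sp_inv <- solve(cov(P_lib))
    md <- sqrt(rowSums((sweep(P_lib, 2L, mu_p) %*% Sp_inv) *
                         sweep(P_lib, 2L, mu_p)))
    G <- m$B %*% M
    list(m = m, BWR = BW %*% m$R, BWN = BW %*% m$N,
         G = G, Gd = drop(G %*% fa$d),
         mu_p = mu_p, Sp_inv = Sp_inv,
         rad = stats::quantile(md, 0.975, names = FALSE))
  }
  clamp_potent <- function(z_r, cb) {
    dd <- z_r - cb$mu_p
    r <- sqrt(drop(dd %*% cb$Sp_inv %*% dd))
    if (r > cb$rad) cb$mu_p + dd * cb$rad / r else z_r
  }
  ctl <- lapply(list(m1, m2), make_ctl)

  # ---- closed-loop trials --------------------------------------------------
  set.seed(derive_seed(config$seed, 5L))
  n_trials <- config$n_trials_map1 + config$n_trials_map2
  mapping_of <- rep(c(1L, 2L), c(config$n_trials_map1, config$n_trials_map2))
  targets_deg <- as.vector(vapply(seq_len(ceiling(n_trials / 8)),
                                  function(i) sample(seq(0, 315, by = 45)),
                                  numeric(8)))[seq_len(n_trials)]

  max_bins <- n_trials * (config$n_freeze + config$max_ctrl_bins)
  counts <- matrix(0L, max_bins, q)
  rec <- list(trial = integer(max_bins), bin = integer(max_bins),
              frozen = logical(max_bins),
              pos_x = numeric(max_bins), pos_y = numeric(max_bins),
              v_x = numeric(max_bins), v_y = numeric(max_bins),
              v_prev_x = numeric(max_bins), v_prev_y = numeric(max_bins),
              theta = numeric(max_bins))
  tr_success <- logical(n_trials)
  tr_time <- numeric(n_trials)
  tr_bins <- integer(n_trials)

  n_clip <- 0L; n_rate <- 0L
  row <- 0L
  # physiological ceiling on the rates the minimal-world subject may command
  u_cap <- 3 * apply(rates_lib, 2L, max)

  for (tr in seq_len(n_trials)) {
    act_id <- mapping_of[tr]
    m2_trial_idx <- tr - config$n_trials_map1
    m_act <- list(m1, m2)[[act_id]]
    cb <- ctl[[act_id]]
    # learning phase: exploratory aiming noise decays across the burn-in
    aim_sd <- config$aim_noise_floor
    if (act_id == 2L && m2_trial_idx <= config$burn_in) {
      frac <- 1 - (m2_trial_idx - 1L) / config$burn_in
      aim_sd <- config$aim_noise_floor +
        (config$aim_noise_deg - config$aim_noise_floor) * frac
    }
    target <- config$target_distance *
      c(cos(targets_deg[tr] * pi / 180), sin(targets_deg[tr] * pi / 180))

    pos <- c(0, 0); v <- c(0, 0)
    success <- FALSE
    nb <- 0L
    for (b in seq_len(config$n_freeze + config$max_ctrl_bins)) {
      frozen <- b <= config$n_freeze
      to_target <- target - pos
      dist <- sqrt(sum(to_target^2))
      sp <- min(config$intended_speed, dist / (3 * bin_s))
      v_int <- if (dist > 1e-9) sp * to_target / dist else c(0, 0)
      if (aim_sd > 0 && !frozen) {
        xi <- rnorm(1L, sd = aim_sd * pi / 180)
        v_int <- c(cos(xi) * v_int[1L] - sin(xi) * v_int[2L],
                   sin(xi) * v_int[1L] + cos(xi) * v_int[2L])
      }
      v_used <- if (frozen) c(0, 0) else v

      rhs <- v_int - drop(A %*% v_used) - cb$m$c
      z_r0 <- clamp_potent(drop(solve(cb$BWR, rhs)), cb)

      if (config$world == "minimal") {
        sol <- min_norm_program(cb$G, rhs + cb$Gd, lower = 0, upper = u_cap)
        if (!sol$feasible) {
          for (tshrink in c(0.5, 0.25, 0.1, 0)) {
            sol <- min_norm_program(cb$G, tshrink * rhs + cb$Gd, lower = 0,
                                    upper = u_cap)
            if (sol$feasible) break
          }
        }
        lam <- sol$u
      } else {
        z_n <- drop(coupling_draw(config$world, matrix(z_r0, 1L), cb$m$N,
                                  cb$m$R, frame, gt$coupling_noise))
        z_r <- clamp_potent(drop(solve(cb$BWR, rhs - drop(cb$BWN %*% z_n))), cb)
        zt <- drop(cb$m$N %*% z_n + cb$m$R %*% z_r)
        mu <- drop(fa$orth_U %*% zt) + fa$d
        n_clip <- n_clip + sum(mu < 0)
        lam <- pmax(mu, 0)
      }
      n_rate <- n_rate + q
      u <- rpois(q, lam)
      z_dec <- drop(M %*% (u - fa$d))

      v_new <- if (frozen) c(0, 0) else
        drop(A %*% v + m_act$B %*% z_dec + m_act$c)

      row <- row + 1L; nb <- nb + 1L
      counts[row, ] <- u
      rec$trial[row] <- tr; rec$bin[row] <- b; rec$frozen[row] <- frozen
      rec$pos_x[row] <- pos[1L]; rec$pos_y[row] <- pos[2L]
      rec$v_prev_x[row] <- v_used[1L]; rec$v_prev_y[row] <- v_used[2L]
      rec$v_x[row] <- v_new[1L]; rec$v_y[row] <- v_new[2L]
      rec$theta[row] <- angle_deg(to_target[1L], to_target[2L])

      v <- v_new
      if (!frozen) {
        pos <- pos + v * bin_s
        if (sqrt(sum((pos - target)^2)) <= config$acquisition_radius) {
          success <- TRUE
          break
        }
      }
    }
    tr_success[tr] <- success
    tr_bins[tr] <- nb
    tr_time[tr] <- if (success) (nb - config$n_freeze) * bin_s else
      config$timeout_s
  }

  if (mean(tr_success[mapping_of == 1L]) < 0.5) {
    stop("mis-configured controller: fewer than 50% of mapping-1 trials succeed")
  }

  keep <- seq_len(row)
  steps <- tibble::tibble(
    t = keep, trial = rec$trial[keep], bin = rec$bin[keep],
    mapping = mapping_of[rec$trial[keep]], frozen = rec$frozen[keep],
    pos_x = rec$pos_x[keep], pos_y = rec$pos_y[keep],
    v_x = rec$v_x[keep], v_y = rec$v_y[keep],
    v_prev_x = rec$v_prev_x[keep], v_prev_y = rec$v_prev_y[keep],
    theta = rec$theta[keep]
  )
  trials <- tibble::tibble(
    trial = seq_len(n_trials), mapping = mapping_of,
    target_deg = targets_deg, success = tr_success,
    acq_time = tr_time, n_bins = tr_bins
  )
  structure(list(
    counts = counts[keep, , drop = FALSE], steps = steps, trials = trials,
    mappings = list(m1, m2), fa = fa, ground_truth = gt, frame = frame,
    calibration_counts = counts_cal,
    clip_fraction = if (n_rate > 0) n_clip / n_rate else 0,
    config = config
  ), class = "bci_session")
}

#' @export
print.bci_session <- function(x, ...) {
  cat("Simulated BCI session (world:", x$config$world, ")\n")
  cat("  ", nrow(x$counts), "bins x", ncol(x$counts), "units;",
      nrow(x$trials), "trials\n")
  for (mp in 1:2) {
    tr <- x$trials[x$trials$mapping == mp, ]
    cat(sprintf("   mapping %d: %d trials, %.0f%% success, median acq %.2f s\n",
                mp, nrow(tr), 100 * mean(tr$success),
                stats::median(tr$acq_time[tr$success])))
  }
  cat(sprintf("   rate clip fraction: %.4f\n", x$clip_fraction))
  invisible(x)
}

#' @export
glance.bci_session <- function(x, ...) {
  tr2 <- x$trials[x$trials$mapping == 2L, ]
  tibble::tibble(
    world = x$config$world, n_bins = nrow(x$counts),
    n_units = ncol(x$counts), n_trials = nrow(x$trials),
    success_map1 = mean(x$trials$success[x$trials$mapping == 1L]),
    success_map2 = mean(tr2$success),
    clip_fraction = x$clip_fraction
  )
}

#' @export
autoplot.bci_session <- function(object, ...) {
  tr <- object$trials
  tr$smoothed <- tryCatch(
    smooth_acquisition_time(tr$acq_time, tr$success, 100L),
    error = function(e) rep(NA_real_, nrow(tr)))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$trial, y = .data$acq_time)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), color = "firebrick") +
    ggplot2::geom_vline(xintercept = sum(tr$mapping == 1L) + 0.5,
                        linetype = 2) +
    ggplot2::labs(x = "trial", y = "acquisition time (s)") +
    ggplot2::theme_minimal()
}
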