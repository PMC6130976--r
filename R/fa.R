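#' Fit a factor-analysis model of the intrinsic manifold
#'
#' Fits the linear-Gaussian factor model \eqn{u_t \sim N(L z_t + d, \Psi)}
#' (with \eqn{z_t \sim N(0, I_k)} and diagonal \eqn{\Psi}) to a matrix of
#' binned spike counts by expectation-maximization, and precomputes the
#' orthonormalized basis \eqn{L = U S V^\top} used to express factor activity
#' in spike-count units.
#'
#' EM is run on the sample covariance of the counts until the relative change
#' in marginal log-likelihood falls below `tol` (or `max_iter` iterations).
#' Initialization is the principal-component loading with a small seeded
#' jitter. Units with (near) zero variance have their noise variance floored
#' at `psi_floor` with a warning.
#'
#' @param counts Numeric matrix, time bins by units, of non-negative spike
#'   counts (a data frame is coerced).
#' @param k Number of factors (default 10, the dimensionality of the
#'   intrinsic manifold).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param seed Integer seed for the jittered initialization.
#' @param psi_floor Lower bound on the per-unit noise variances.
#'
#' @return An object of class `fa_model`: a list with the loading matrix
#'   `L` (units x k), noise variances `psi`, baseline `d`, the orthonormal
#'   factors of the loading (`orth_U`, `orth_S`, `orth_V`), the
#'   log-likelihood trace `loglik`, and convergence information.
#' @export
fit_fa <- function(counts, k = 10, tol = 1e-8, max_iter = 5000, seed = 1L,
                   psi_floor = 1e-6) {
  X <- as.matrix(counts)
  storage.mode(X) <- "double"
  n <- nrow(X)
  q <- ncol(X)
  stopifnot(n > q, k < q, k >= 1)
  if (anyNA(X)) stop("counts contain missing values")

  d <- colMeans(X)
  Xc <- sweep(X, 2L, d)
  S <- crossprod(Xc) / n

  dv <- diag(S)
  if (any(dv <= psi_floor)) {
    warning("unit(s) with (near) zero variance; noise variance floored")
  }

  # PCA initialization with small seeded jitter
  es <- eigen(S, symmetric = TRUE)
  ev <- pmax(es$values[seq_len(k)], psi_floor)
  set.seed(derive_seed(seed, 11L))
  L <- es$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k) +
    matrix(rnorm(q * k, sd = 1e-3), q, k)
  psi <- pmax(dv - rowSums(L^2), psi_floor)

  const <- -0.5 * n * q * log(2 * pi)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    # Woodbury pieces: beta = L'(LL'+Psi)^{-1} = Mk^{-1} L' Psi^{-1}
    Lp <- L / psi                               # Psi^{-1} L  (q x k)
    Mk <- diag(k) + crossprod(L, Lp)            # I + L'Psi^{-1}L
    Mk_chol <- chol(Mk)
    beta <- backsolve(Mk_chol, forwardsolve(t(Mk_chol), t(Lp)))  # k x q

    # log-likelihood of current parameters
    bS <- beta %*% S                            # k x q
    tr_SinvS <- sum(dv / psi) - sum(bS * t(Lp))
    logdet <- 2 * sum(log(diag(Mk_chol))) + sum(log(psi))
    ll <- const - 0.5 * n * (logdet + tr_SinvS)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) <= tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll

    # M-step
    Ezz <- chol2inv(Mk_chol) + bS %*% t(beta)   # k x k (per-sample average)
    L <- t(solve(Ezz, bS))                      # q x k
    psi <- pmax(dv - rowSums(L * t(bS)), psi_floor)
  }

  sv <- svd(L)
  sgn <- apply(sv$u, 2L, first_nonzero_sign)
  orth_U <- sweep(sv$u, 2L, sgn, `*`)
  orth_V <- sweep(sv$v, 2L, sgn, `*`)

  structure(list(
    L = L, psi = psi, d = d,
    orth_U = orth_U, orth_S = sv$d, orth_V = orth_V,
    k = k, n_obs = n,
    loglik = ll_trace, converged = converged, n_iter = length(ll_trace)
  ), class = "fa_model")
}

first_nonzero_sign <- function(x, tol = 1e-9) {
  i <- which(abs(x) > tol * max(abs(x), tol))[1L]
  if (is.na(i) || x[i] >= 0) 1 else -1
}

#' Posterior mean of the (raw) factor activity
#'
#' Evaluates \eqn{z_t = L^\top (L L^\top + \Psi)^{-1} (u_t - d)}, the posterior
#' expectation of the factors given a spike-count vector, before
#' orthonormalization.
#'
#' @param u A count vector of length `q`, or a time-by-units matrix.
#' @param model An [fit_fa()] model.
#' @return A factor vector of length `k` (or a time-by-`k` matrix).
#' @export
posterior_factors <- function(u, model) {
  beta <- fa_posterior_matrix(model)
  if (is.matrix(u)) {
    sweep(u, 2L, model$d) %*% t(beta)
  } else {
    drop(beta %*% (u - model$d))
  }
}

# beta = L'(LL'+Psi)^{-1}, computed stably via the Woodbury identity
fa_posterior_matrix <- function(model) {
  L <- model$L
  Lp <- L / model$psi
  Mk <- diag(ncol(L)) + crossprod(L, Lp)
  solve(Mk, t(Lp))
}

#' Orthonormalize raw factor activity
#'
#' Converts raw posterior factors to the orthonormalized convention
#' \eqn{\tilde z = S V^\top z} so that \eqn{L z = U \tilde z}; the
#' orthonormalized factors have spike-count-per-bin units.
#'
#' @param z_raw Raw factor vector (length `k`) or matrix (time by `k`).
#' @param model An [fit_fa()] model.
#' @return Orthonormalized factor activity with the shape of `z_raw`.
#' @export
orthonormalize_factors <- function(z_raw, model) {
  Tm <- diag(model$orth_S, model$k) %*% t(model$orth_V)
  if (is.matrix(z_raw)) z_raw %*% t(Tm) else drop(Tm %*% z_raw)
}

#' Map spike counts to orthonormalized factor activity
#'
#' Composition of [posterior_factors()] and [orthonormalize_factors()]; the
#' linear map `f(u)` through which all analyses view the population activity.
#'
#' @inheritParams posterior_factors
#' @return Orthonormalized factor activity.
#' @export
counts_to_factors <- function(u, model) {
  orthonormalize_factors(posterior_factors(u, model), model)
}

# f(u) = M (u - d) with M = S V' beta; returns the k x q matrix M
factor_map_matrix <- function(model) {
  diag(model$orth_S, model$k) %*% t(model$orth_V) %*% fa_posterior_matrix(model)
}

#' @export
print.fa_model <- function(x, ...) {
  cat("Factor-analysis model: ", length(x$d), " units, ", x$k, " factors\n",
      "  EM iterations: ", x$n_iter,
      if (x$converged) " (converged)" else " (max iterations reached)", "\n",
      "  final log-likelihood: ", format(tail(x$loglik, 1L)), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.fa_model <- function(x, ...) {
  tibble::tibble(
    factor = rep(seq_len(x$k), each = length(x$d)),
    unit = rep(seq_along(x$d), times = x$k),
    loading = as.vector(x$L)
  )
}

#' @export
glance.fa_model <- function(x, ...) {
  tibble::tibble(
    n_units = length(x$d), k = x$k, n_obs = x$n_obs,
    loglik = tail(x$loglik, 1L), n_iter = x$n_iter, converged = x$converged,
    shared_variance = sum(x$orth_S^2),
    noise_variance = sum(x$psi)
  )
}
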