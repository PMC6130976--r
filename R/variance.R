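# Variance of activity in dimensions that switch potency between mappings,
# and the mean-shift comparison against the minimal hypotheses.

#' Subspace that was output-potent under mapping 1 but output-null under
#' mapping 2
#'
#' An orthonormal basis (via SVD) of \eqn{(N_2 N_2^\top) R_1}: the projection
#' of the first mapping's row space into the second mapping's null space.
#' Singular values below `tol` times the largest are treated as zero; a rank
#' below 2 is flagged with a warning, rank 0 is an error (e.g. when the two
#' mappings coincide).
#'
#' @param m1,m2 [bci_mapping()]s sharing the factor dimension.
#' @param tol Relative rank tolerance.
#' @return A list of class `subspace_basis` with the k x r `basis`, its
#'   `rank`, and the `singular_values`.
#' @export
overlap_subspace <- function(m1, m2, tol = 1e-10) {
  stopifnot(m1$k == m2$k)
  P <- m2$N %*% crossprod(m2$N, m1$R)
  sv <- svd(P)
  # singular values are cosines of principal angles, bounded by 1
  keep <- sv$d > tol
  r <- sum(keep)
  if (r == 0L) stop("rank-0 overlap: no mapping-1 potent direction lies in the mapping-2 null space")
  if (r < ncol(m1$R)) warning("overlap subspace has rank ", r, " < 2")
  basis <- sweep(sv$u[, keep, drop = FALSE], 2L,
                 apply(sv$u[, keep, drop = FALSE], 2L, first_nonzero_sign), `*`)
  structure(list(basis = basis, rank = r, singular_values = sv$d),
            class = "subspace_basis")
}

#' Total variance of activity in a subspace
#'
#' \eqn{Trace(Cov(Z S))} for activity `Z` (n x k) and subspace basis `S`.
#'
#' @param Z Activity matrix, rows are time steps.
#' @param S A [overlap_subspace()] result or a k x r basis matrix.
#' @return A non-negative real.
#' @export
subspace_variance <- function(Z, S) {
  B <- if (inherits(S, "subspace_basis")) S$basis else as.matrix(S)
  stopifnot(nrow(Z) >= 3L)
  sum(diag(cov(Z %*% B)))
}

#' Log variance ratio in the potency-switching subspace
#'
#' Per cursor-direction bin, \eqn{R = \log(Trace(Cov(Z_2 S)) /
#' Trace(Cov(Z_1 S)))}: positive when variance grew after those dimensions
#' became output-null, negative when it shrank. Both activity sets are binned
#' by the cursor movement angle computed through the *second* mapping as
#' \eqn{v = B_2 z + c_2} (previous-velocity term dropped), so first- and
#' second-mapping steps are conditioned identically.
#'
#' @param Z1 Factor activity recorded under mapping 1 (n1 x k).
#' @param Z2 Factor activity under mapping 2 — observed, or a hypothesis's
#'   predicted null activity recombined with the observed potent activity
#'   (n2 x k).
#' @param S A [overlap_subspace()] basis.
#' @param m2 The second mapping (used for the direction binning).
#' @param min_bin Minimum steps per bin on each side; smaller bins are
#'   omitted.
#' @return A list of class `variance_ratio` with a per-direction tibble and
#'   the session `average`.
#' @export
variance_ratio <- function(Z1, Z2, S, m2, min_bin = 3L) {
  b1 <- bin_timesteps(instantaneous_angle(Z1, m2), angles = TRUE)
  b2 <- bin_timesteps(instantaneous_angle(Z2, m2), angles = TRUE)
  centers <- seq(0, 315, by = 45)
  rows <- lapply(centers, function(ct) {
    i1 <- which(!is.na(b1) & b1 == ct)
    i2 <- which(!is.na(b2) & b2 == ct)
    if (length(i1) < min_bin || length(i2) < min_bin) return(NULL)
    t1 <- subspace_variance(Z1[i1, , drop = FALSE], S)
    t2 <- subspace_variance(Z2[i2, , drop = FALSE], S)
    if (t1 <= 0 || t2 <= 0) return(NULL)
    tibble::tibble(direction = ct, ratio = log(t2 / t1),
                   n1 = length(i1), n2 = length(i2))
  })
  tbl <- dplyr::bind_rows(rows)
  if (nrow(tbl) == 0L) stop("no direction bin populated on both sides")
  structure(list(directions = tbl, average = mean(tbl$ratio)),
            class = "variance_ratio")
}

#' @export
print.variance_ratio <- function(x, ...) {
  cat(sprintf("Subspace variance ratio: session average %.3f over %d direction bins\n",
              x$average, nrow(x$directions)))
  invisible(x)
}

#' Recombine predicted output-null activity with observed potent activity
#'
#' Builds the full factor patterns \eqn{N \hat z^n + R z^r} used when a
#' hypothesis's predictions stand in for the second-mapping activity in the
#' variance-ratio analysis. Skipped steps are dropped.
#'
#' @param ps A `prediction_set`.
#' @param ctx The [prediction_context()] it was computed from.
#' @return A matrix (n_kept x k).
#' @export
recombine_predictions <- function(ps, ctx) {
  keep <- !ps$steps$skipped
  m <- ctx$map_eval
  ps$pred[keep, , drop = FALSE] %*% t(m$N) +
    ctx$z_r_eval[keep, , drop = FALSE] %*% t(m$R)
}

#' Distances of mean output-null activity from a minimal hypothesis
#'
#' Per direction bin, compares the distance from the observed mean
#' output-null activity to a minimal hypothesis's mean, against the distance
#' from the Fixed Distribution mean to the same minimal mean, with a
#' one-sided Wilcoxon signed-rank test of whether the observed means lie
#' closer to the minimal means than the Fixed Distribution account predicts.
#'
#' @param mu_obs,mu_fd,mu_min Matrices of per-direction mean output-null
#'   vectors (8 x p): observed, Fixed Distribution, and a minimal hypothesis
#'   (Minimal Firing or Minimal Deviation).
#' @return A list with a per-direction tibble of paired distances and the
#'   one-sided signed-rank `p_value`.
#' @export
mean_shift_analysis <- function(mu_obs, mu_fd, mu_min) {
  stopifnot(all(dim(mu_obs) == dim(mu_fd)), all(dim(mu_obs) == dim(mu_min)))
  d_obs <- sqrt(rowSums((mu_obs - mu_min)^2))
  d_fd <- sqrt(rowSums((mu_fd - mu_min)^2))
  pv <- if (all(d_obs == d_fd)) 1 else
    suppressWarnings(wilcox.test(d_obs, d_fd, paired = TRUE,
                                 alternative = "less")$p.value)
  list(directions = tibble::tibble(direction = seq_len(nrow(mu_obs)),
                                   dist_obs_min = d_obs, dist_fd_min = d_fd),
       p_value = pv)
}
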