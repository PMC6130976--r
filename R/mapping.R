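#' Construct a BCI velocity mapping
#'
#' A mapping is the affine dynamical readout \eqn{v_t = A v_{t-1} + B z_t + c}
#' from orthonormalized factor activity to 2-D cursor velocity, together with
#' orthonormal bases for the null space (`N`, k x (k-2)) and row space
#' (`R`, k x 2) of `B`.
#'
#' @param A 2x2 velocity smoothing matrix.
#' @param B 2xk readout matrix (must have rank 2).
#' @param c Length-2 offset vector.
#' @return An object of class `bci_mapping`.
#' @export
bci_mapping <- function(A, B, c) {
  A <- as.matrix(A); B <- as.matrix(B); c <- as.numeric(c)
  stopifnot(identical(dim(A), c(2L, 2L)), nrow(B) == 2L, length(c) == 2L,
            ncol(B) >= 3L)
  nb <- null_potent_bases(B)
  structure(list(A = A, B = B, c = c, N = nb$N, R = nb$R, k = ncol(B)),
            class = "bci_mapping")
}

#' Orthonormal null-space and row-space bases of a readout matrix
#'
#' Takes the SVD \eqn{B = U S V^\top} (singular values ordered so the two
#' nonzero ones come first); the first two right singular vectors span the row
#' space, the remaining k-2 the null space. A deterministic sign rule (first
#' nonzero entry of each column positive) fixes the SVD sign freedom so that
#' serialized bases are reproducible; every reported quantity is invariant to
#' this choice.
#'
#' @param B 2xk matrix of rank 2.
#' @return A list with orthonormal `N` (k x (k-2)) and `R` (k x 2).
#' @export
null_potent_bases <- function(B) {
  B <- as.matrix(B)
  stopifnot(nrow(B) == 2L)
  k <- ncol(B)
  sv <- svd(B, nu = 2L, nv = k)
  if (sv$d[2L] <= 1e-10 * sv$d[1L]) stop("readout matrix B has rank < 2")
  V <- sv$v
  V <- sweep(V, 2L, apply(V, 2L, first_nonzero_sign), `*`)
  list(R = V[, 1:2, drop = FALSE], N = V[, -(1:2), drop = FALSE])
}

#' Decode cursor velocity from factor activity
#'
#' Exact affine evaluation \eqn{v_t = A v_{t-1} + B z_t + c}.
#'
#' @param z Factor vector (length k) or time-by-k matrix.
#' @param v_prev Previous velocity: length-2 vector, or time-by-2 matrix when
#'   `z` is a matrix.
#' @param m A [bci_mapping()].
#' @return Velocity: length-2 vector or time-by-2 matrix.
#' @export
decode_velocity <- function(z, v_prev, m) {
  if (is.matrix(z)) {
    vp <- if (is.matrix(v_prev)) v_prev else
      matrix(v_prev, nrow(z), 2L, byrow = TRUE)
    vp %*% t(m$A) + z %*% t(m$B) + matrix(m$c, nrow(z), 2L, byrow = TRUE)
  } else {
    drop(m$A %*% v_prev + m$B %*% z + m$c)
  }
}

#' Permute a mapping within the intrinsic manifold
#'
#' Builds the within-manifold perturbation: the elements of \eqn{z_t} are
#' permuted before the readout, which is equivalent to reordering the columns
#' of `B` (`A` and `c` unchanged). Null and row bases are recomputed.
#'
#' @param m A [bci_mapping()].
#' @param perm A permutation of `1:k`; the permuted readout evaluates
#'   `B %*% z[perm]`.
#' @return A new `bci_mapping`.
#' @export
permute_mapping <- function(m, perm) {
  k <- m$k
  stopifnot(length(perm) == k, setequal(perm, seq_len(k)))
  if (all(perm == seq_len(k))) stop("perm is the identity: no perturbation")
  # B_new z = B z[perm]  =>  B_new[, j] = B[, perm^{-1}(j)]
  inv <- match(seq_len(k), perm)
  bci_mapping(m$A, m$B[, inv, drop = FALSE], m$c)
}

#' Split factor activity into output-potent and output-null components
#'
#' Orthogonal projections \eqn{z^n = N^\top z}, \eqn{z^r = R^\top z}; the
#' reconstruction \eqn{z = N z^n + R z^r} holds exactly.
#'
#' @param z Factor vector or time-by-k matrix.
#' @param m A [bci_mapping()].
#' @return A list with `z_r` (potent) and `z_n` (null), vectors or matrices
#'   matching the input shape.
#' @export
split_activity <- function(z, m) {
  if (is.matrix(z)) {
    list(z_r = z %*% m$R, z_n = z %*% m$N)
  } else {
    list(z_r = drop(crossprod(m$R, z)), z_n = drop(crossprod(m$N, z)))
  }
}

#' Instantaneous cursor-movement angle of factor activity
#'
#' The angle (degrees counterclockwise from +x, in [0, 360)) of
#' \eqn{v = B z + c}, the velocity contribution of the activity itself
#' (previous-velocity term dropped). Numerically zero vectors are flagged
#' `NA` so the time step can be excluded from direction binning.
#'
#' @param z Factor vector or time-by-k matrix.
#' @param m A [bci_mapping()].
#' @param tol Norm below which the velocity is treated as zero.
#' @return Angle(s) in degrees, `NA` where undefined.
#' @export
instantaneous_angle <- function(z, m, tol = 1e-12) {
  v <- if (is.matrix(z)) {
    z %*% t(m$B) + matrix(m$c, nrow(z), 2L, byrow = TRUE)
  } else {
    matrix(drop(m$B %*% z + m$c), 1L, 2L)
  }
  ang <- angle_deg(v[, 1L], v[, 2L], tol = tol)
  if (is.matrix(z)) ang else ang[1L]
}

# atan2 in degrees, mapped to [0, 360); NA for (numerically) zero vectors
angle_deg <- function(x, y, tol = 1e-12) {
  a <- atan2(y, x) * 180 / pi
  a <- a %% 360
  a[sqrt(x^2 + y^2) < tol] <- NA_real_
  a
}

#' @export
print.bci_mapping <- function(x, ...) {
  cat("BCI mapping: k =", x$k, "factors -> 2-D velocity\n")
  cat("  singular values of B:", format(svd(x$B)$d, digits = 4), "\n")
  invisible(x)
}
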