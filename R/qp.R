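# Minimum-norm spike-count programs.
#
# The Minimal Firing predictor solves, at every time step,
#   min ||u||^2  s.t.  G u = b,  0 <= u <= umax
# with G the 2 x q composite map from counts to readout velocity. The
# equality-constraint dual is 2-dimensional and concave with
# u(nu) = clip(G' nu / 2, lb, ub), so we maximize it by BFGS and then polish
# with an exact KKT solve on the free coordinate set. This is exact (verified
# against a stock active-set QP solver in the tests) and fast enough to run
# once per analyzed time step.

#' Minimum-norm solution under equality and box constraints
#'
#' Solves `min ||u||_2^2` (or `min sum(u)` when `norm = "l1"` and `lower >= 0`)
#' subject to `G u = b` and `lower <= u <= upper`.
#'
#' @param G Constraint matrix (m x q, m small).
#' @param b Right-hand side (length m).
#' @param lower,upper Box bounds (length q or scalars).
#' @param norm `"l2"` (quadratic objective) or `"l1"`.
#' @param tol Feasibility tolerance on `||G u - b||`.
#' @return A list with the solution `u`, the achieved `residual`, the
#'   objective `value`, and `feasible` (FALSE when the equality constraint
#'   cannot be met inside the box).
#' @export
min_norm_program <- function(G, b, lower = 0, upper = Inf, norm = c("l2", "l1"),
                             tol = 1e-6) {
  norm <- match.arg(norm)
  G <- as.matrix(G)
  q <- ncol(G)
  lb <- rep_len(lower, q)
  ub <- rep_len(upper, q)
  if (norm == "l1") return(min_l1_program(G, b, lb, ub, tol))

  uofnu <- function(nu) pmin(pmax(drop(crossprod(G, nu)) / 2, lb), ub)
  neg_dual <- function(nu) {
    u <- uofnu(nu)
    -(sum(u * u) - sum(nu * (drop(G %*% u) - b)))
  }
  neg_grad <- function(nu) drop(G %*% uofnu(nu)) - b
  o <- optim(numeric(nrow(G)), neg_dual, neg_grad, method = "BFGS",
             control = list(maxit = 500L, reltol = 1e-14))
  u <- uofnu(o$par)

  # KKT polish: exact equality solve on the free set, clamped, iterated
  for (it in seq_len(25L)) {
    free <- u > lb + 1e-9 & u < ub - 1e-9
    if (sum(free) < nrow(G)) break
    Gf <- G[, free, drop = FALSE]
    GG <- tcrossprod(Gf)
    if (rcond(GG) < 1e-14) break
    rhs <- b - drop(G[, !free, drop = FALSE] %*% u[!free])
    uf <- drop(crossprod(Gf, solve(GG, rhs)))
    clamped <- pmin(pmax(uf, lb[free]), ub[free])
    u[free] <- clamped
    if (max(abs(uf - clamped)) < 1e-12) break
  }
  resid <- max(abs(drop(G %*% u) - b))
  list(u = u, residual = resid, value = sum(u * u), feasible = resid <= tol)
}

min_l1_program <- function(G, b, lb, ub, tol) {
  if (any(lb < 0)) stop("l1 objective requires non-negative lower bounds")
  ubf <- ifelse(is.finite(ub), ub, 1e9)
  # shift to x = u - lb >= 0 for the LP solver
  sol <- tryCatch(
    pracma::linprog(cc = rep(1, ncol(G)),
                    Aeq = G, beq = b - drop(G %*% lb),
                    A = rbind(diag(ncol(G))), b = ubf - lb,
                    maxiter = 100L * ncol(G)),
    error = function(e) NULL)
  if (is.null(sol) || is.null(sol$x)) {
    return(list(u = rep(NA_real_, ncol(G)), residual = Inf, value = NA_real_,
                feasible = FALSE))
  }
  u <- sol$x + lb
  resid <- max(abs(drop(G %*% u) - b))
  list(u = u, residual = resid, value = sum(u), feasible = resid <= tol)
}
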