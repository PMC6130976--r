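# Scoring predicted against observed output-null distributions.

#' Assign time steps to cursor-direction bins
#'
#' Eight non-overlapping wedges centered at 0, 45, ..., 315 degrees with
#' half-width 22.5; assignment is half-open, `[center - 22.5, center + 22.5)`,
#' so an angle of exactly 22.5 falls in the 45-degree bin. Zero-velocity
#' steps get `NA`.
#'
#' @param v Velocity matrix (n x 2), or a vector of angles in degrees when
#'   `angles = TRUE`.
#' @param angles Interpret `v` as precomputed angles.
#' @return Numeric vector of bin centers (degrees), `NA` where undefined.
#' @export
bin_timesteps <- function(v, angles = FALSE) {
  a <- if (angles) as.numeric(v) %% 360 else angle_deg(v[, 1L], v[, 2L])
  (floor((a + 22.5) / 45) * 45) %% 360
}

#' Cross-validated histogram bin width
#'
#' Selects a single bin width for all of a session's histograms by
#' minimizing the unbiased leave-one-out cross-validation risk of the
#' histogram density estimator,
#' \eqn{J(h) = 2/((n-1)h) - (n+1)/((n-1)h) \sum_j p_j^2},
#' over a geometric grid of `n_widths` candidates centered on the normal
#' reference width \eqn{3.49 \sigma n^{-1/3}} (the grid is built from the
#' sample scale, so the selected width is scale-equivariant). Bin edges are
#' anchored at zero.
#'
#' @param x Pooled output-null samples (all included steps and dimensions).
#' @param n_widths Number of candidate widths.
#' @param span Log-range factor of the grid around the reference width.
#' @return The selected width.
#' @export
select_bin_width <- function(x, n_widths = 30L, span = 16) {
  x <- as.numeric(x[is.finite(x)])
  n <- length(x)
  stopifnot(n >= 100L)
  s <- sd(x)
  if (!is.finite(s) || s <= 0) stop("degenerate (zero-variance) data")
  h0 <- 3.49 * s * n^(-1 / 3)
  grid <- exp(seq(log(h0 / span), log(h0 * span), length.out = n_widths))
  risks <- vapply(grid, function(h) histogram_cv_risk(x, h), numeric(1))
  grid[which.min(risks)]
}

#' Leave-one-out histogram risk for one bin width
#'
#' @param x Numeric sample.
#' @param h Bin width (> 0), edges anchored at zero.
#' @return The unbiased LOO risk estimate.
#' @export
histogram_cv_risk <- function(x, h) {
  n <- length(x)
  counts <- tabulate(bin_index(x, h) - min(bin_index(x, h)) + 1L)
  p <- counts / n
  2 / ((n - 1) * h) - (n + 1) / ((n - 1) * h) * sum(p^2)
}

# index of the zero-anchored bin [i*h, (i+1)*h) containing x
bin_index <- function(x, h) as.integer(floor(x / h))

#' Build a normalized histogram on zero-anchored edges
#'
#' @param x Numeric sample.
#' @param h Bin width.
#' @param lo,hi Range the edges must cover (defaults to the sample range).
#' @return A `null_histogram`: edges, normalized masses, and sample count.
#' @export
null_histogram <- function(x, h, lo = min(x), hi = max(x)) {
  stopifnot(h > 0, length(x) > 0L)
  i0 <- as.integer(floor(lo / h))
  i1 <- as.integer(floor(hi / h))
  idx <- pmin(pmax(bin_index(x, h), i0), i1)
  mass <- tabulate(idx - i0 + 1L, nbins = i1 - i0 + 1L) / length(x)
  structure(list(edges = seq(i0, i1 + 1L) * h, mass = mass, n = length(x)),
            class = "null_histogram")
}

#' Histogram error (half total-variation distance)
#'
#' \eqn{L(y, \hat y) = \frac{1}{2}\sum_i |y_i - \hat y_i|} between two
#' normalized histograms built on identical edges: 0 for identical
#' histograms, 1 for completely disjoint supports.
#'
#' @param y,yhat `null_histogram`s with identical edges.
#' @return A fraction in [0, 1].
#' @export
histogram_error <- function(y, yhat) {
  stopifnot(inherits(y, "null_histogram"), inherits(yhat, "null_histogram"))
  if (length(y$edges) != length(yhat$edges) ||
      max(abs(y$edges - yhat$edges)) > 1e-9) {
    stop("histograms must share identical edges")
  }
  0.5 * sum(abs(y$mass - yhat$mass))
}

#' Mean error
#'
#' Euclidean distance between observed and predicted mean output-null
#' vectors.
#'
#' @param mu,mu_hat Numeric vectors of equal length.
#' @return A non-negative real.
#' @export
mean_error <- function(mu, mu_hat) {
  stopifnot(length(mu) == length(mu_hat))
  sqrt(sum((mu - mu_hat)^2))
}

#' Affine-invariant covariance error
#'
#' The Förstner metric between two symmetric positive-definite matrices:
#' \eqn{\sqrt{\sum_i \log^2 \lambda_i}} over the generalized eigenvalues
#' \eqn{\det(C - \lambda \hat C) = 0}. Invariant to any common affine
#' transformation of the coordinates. A small ridge
#' (`ridge * trace(C)/dim`) is added to each matrix, but only when the plain
#' decomposition fails (numerical safety without perturbing well-conditioned
#' inputs). `squared = TRUE` returns
#' \eqn{\sum_i \log^2 \lambda_i} instead (a monotone transform; hypothesis
#' rankings are unaffected).
#'
#' @param C,C_hat Symmetric PSD matrices of equal dimension.
#' @param ridge Relative ridge added to each matrix.
#' @param squared Return the sum of squared log-eigenvalues without the
#'   square root.
#' @return A non-negative real.
#' @export
covariance_error <- function(C, C_hat, ridge = 1e-8, squared = FALSE) {
  stopifnot(all(dim(C) == dim(C_hat)))
  if (max(abs(C - C_hat)) == 0) return(0)
  p <- nrow(C)
  gen_eigs <- function(Co, Ch) {
    Rch <- tryCatch(chol(Ch), error = function(e) NULL)
    if (is.null(Rch)) return(NULL)
    # whiten: eigenvalues of R^-T C R^-1 are the generalized eigenvalues
    W <- backsolve(Rch, t(backsolve(Rch, Co, transpose = TRUE)),
                   transpose = TRUE)
    lam <- eigen((W + t(W)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (any(lam <= 0)) NULL else lam
  }
  lam <- gen_eigs(C, C_hat)
  if (is.null(lam)) {
    lam <- gen_eigs(C + diag(ridge * sum(diag(C)) / p, p),
                    C_hat + diag(ridge * sum(diag(C_hat)) / p, p))
  }
  if (is.null(lam)) stop("covariance matrices not positive definite after ridge")
  s <- sum(log(lam)^2)
  if (squared) s else sqrt(s)
}

# ---- session-level scoring -------------------------------------------------

#' Score predicted output-null activity against observed activity
#'
#' Groups observed and predicted steps into the eight cursor-direction bins
#' and computes, per (direction, dimension) cell, the histogram error on
#' shared zero-anchored edges of width `h`, and per direction the mean and
#' covariance errors. Cells whose observed or predicted side is empty are
#' omitted (covariance additionally requires at least `dim + 1` steps).
#'
#' @param obs Observed output-null matrix (n_obs x p).
#' @param pred Predicted output-null matrix (n_pred x p; `NA` rows are
#'   dropped).
#' @param bins_obs,bins_pred Direction-bin labels (centers in degrees) for
#'   the rows of `obs` / `pred`.
#' @param h Shared histogram bin width (see [select_bin_width()]).
#' @return A list of class `null_score` with per-cell and per-direction
#'   tibbles and the session-level summary: `hist_pct` (mean cell error x
#'   100), `mean_err` (factor units per bin), `cov_err`.
#' @export
score_null_predictions <- function(obs, pred, bins_obs, bins_pred, h) {
  p <- ncol(obs)
  keep <- stats::complete.cases(pred) & !is.na(bins_pred)
  pred <- pred[keep, , drop = FALSE]
  bins_pred <- bins_pred[keep]
  oko <- !is.na(bins_obs)
  obs <- obs[oko, , drop = FALSE]
  bins_obs <- bins_obs[oko]

  centers <- seq(0, 315, by = 45)
  cells <- vector("list", 8L * p)
  dirs <- vector("list", 8L)
  for (bi in seq_along(centers)) {
    ct <- centers[bi]
    io <- bins_obs == ct
    ip <- bins_pred == ct
    no <- sum(io); np <- sum(ip)
    if (no == 0L || np == 0L) next
    O <- obs[io, , drop = FALSE]
    P <- pred[ip, , drop = FALSE]
    he <- numeric(p)
    for (j in seq_len(p)) {
      lo <- min(O[, j], P[, j]); hi <- max(O[, j], P[, j])
      he[j] <- histogram_error(null_histogram(O[, j], h, lo, hi),
                               null_histogram(P[, j], h, lo, hi))
    }
    cells[[bi]] <- tibble::tibble(direction = ct, dim = seq_len(p),
                                  hist_err = he, n_obs = no, n_pred = np)
    me <- mean_error(colMeans(O), colMeans(P))
    ce <- if (no > p && np > p) {
      tryCatch(covariance_error(cov(O), cov(P)), error = function(e) NA_real_)
    } else NA_real_
    dirs[[bi]] <- tibble::tibble(direction = ct, mean_err = me, cov_err = ce,
                                 n_obs = no, n_pred = np)
  }
  cell_tbl <- dplyr::bind_rows(cells)
  dir_tbl <- dplyr::bind_rows(dirs)
  if (nrow(cell_tbl) == 0L) stop("no direction bin has both observed and predicted steps")
  structure(list(
    cells = cell_tbl, directions = dir_tbl, h = h,
    hist_pct = 100 * mean(cell_tbl$hist_err),
    mean_err = mean(dir_tbl$mean_err),
    cov_err = mean(dir_tbl$cov_err, na.rm = TRUE)
  ), class = "null_score")
}

#' @export
print.null_score <- function(x, ...) {
  cat(sprintf("Output-null prediction score: histogram %.1f%%, mean %.3f (counts/bin), covariance %.3f\n",
              x$hist_pct, x$mean_err, x$cov_err))
  invisible(x)
}

#' Split-half error floors
#'
#' Estimates the smallest errors achievable given finite sampling: the
#' observed second-mapping steps are randomly split in half `n_reps` times;
#' one half predicts the other half's histograms, means, and covariances
#' with the same shared bin width.
#'
#' @param obs Observed output-null matrix.
#' @param bins Direction-bin labels for its rows.
#' @param h Shared histogram bin width.
#' @param n_reps Number of random splits.
#' @param seed Seed for the splits.
#' @return A tibble with one row per metric: `floor_mean` and `floor_sd`
#'   over repetitions (histogram floor on the percent scale).
#' @export
error_floor <- function(obs, bins, h, n_reps = 100L, seed = 1L) {
  set.seed(derive_seed(seed, 97L))
  n <- nrow(obs)
  stopifnot(n >= 8L)
  hist_v <- mean_v <- cov_v <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    half <- sample.int(n, n %/% 2L)
    sc <- score_null_predictions(obs[half, , drop = FALSE],
                                 obs[-half, , drop = FALSE],
                                 bins[half], bins[-half], h)
    hist_v[r] <- sc$hist_pct
    mean_v[r] <- sc$mean_err
    cov_v[r] <- sc$cov_err
  }
  tibble::tibble(
    metric = c("histogram", "mean", "covariance"),
    floor_mean = c(mean(hist_v), mean(mean_v), mean(cov_v, na.rm = TRUE)),
    floor_sd = c(sd(hist_v), sd(mean_v), sd(cov_v, na.rm = TRUE))
  )
}

#' PCA ordering of the output-null dimensions for display
#'
#' Rotation of the observed output-null activity ordering dimensions by
#' shared variance. Display-only: all error computations use the unrotated
#' null basis.
#'
#' @param obs Observed output-null matrix (n x p, n > p).
#' @return A list with the orthogonal `rotation`, per-component
#'   `var_explained`, and the implied `order` of the original dimensions by
#'   loading magnitude.
#' @export
display_pca_order <- function(obs) {
  stopifnot(nrow(obs) > ncol(obs))
  pc <- prcomp(obs, center = TRUE, scale. = FALSE)
  list(rotation = pc$rotation,
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       order = apply(abs(pc$rotation), 2L, which.max))
}

#' Evaluate a set of hypotheses on a session
#'
#' Runs the full scoring pipeline for one prediction direction: bins the
#' evaluation steps by their recorded cursor velocities, selects the shared
#' histogram width from the pooled observed output-null activity, scores
#' every supplied prediction set, and estimates the split-half floors.
#'
#' @param ctx A [prediction_context()].
#' @param predictions A list of `prediction_set`s from [run_hypothesis()].
#' @param n_floor_reps Split-half repetitions for the floor.
#' @param seed Seed for the floor splits.
#' @param bin_s Bin duration in seconds; mean errors are also reported as
#'   spikes/s by dividing by this value.
#' @return An `error_report`: a tidy per-hypothesis tibble plus floors,
#'   the shared width `h`, and the per-hypothesis `null_score` objects.
#' @export
evaluate_predictions <- function(ctx, predictions, n_floor_reps = 100L,
                                 seed = 1L, bin_s = 0.045) {
  obs <- ctx$z_n_obs
  bins <- bin_timesteps(ctx$v_eval)
  h <- select_bin_width(as.numeric(obs))
  scores <- lapply(predictions, function(ps) {
    score_null_predictions(obs, ps$pred, bins, bins, h)
  })
  names(scores) <- vapply(predictions, `[[`, "", "hypothesis")
  floors <- error_floor(obs, bins, h, n_reps = n_floor_reps, seed = seed)
  summary <- dplyr::bind_rows(lapply(seq_along(scores), function(i) {
    tibble::tibble(
      hypothesis = names(scores)[i],
      hist_pct = scores[[i]]$hist_pct,
      mean_err = scores[[i]]$mean_err,
      mean_err_spikes_s = scores[[i]]$mean_err / bin_s,
      cov_err = scores[[i]]$cov_err,
      skip_fraction = predictions[[i]]$skip_fraction
    )
  }))
  structure(list(summary = summary, floors = floors, h = h, scores = scores,
                 direction = ctx$direction, bin_s = bin_s),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("Output-null prediction errors (direction:", x$direction, ")\n")
  print(as.data.frame(x$summary), digits = 3)
  cat("Floors:\n")
  print(as.data.frame(x$floors), digits = 3)
  invisible(x)
}

#' @export
tidy.error_report <- function(x, ...) {
  x$summary |>
    tidyr::pivot_longer(c("hist_pct", "mean_err", "mean_err_spikes_s", "cov_err"),
                        names_to = "metric", values_to = "value")
}

#' @export
glance.error_report <- function(x, ...) {
  best <- x$summary$hypothesis[which.min(x$summary$hist_pct)]
  tibble::tibble(
    n_hypotheses = nrow(x$summary), h = x$h, direction = x$direction,
    best_hypothesis = best,
    floor_hist_pct = x$floors$floor_mean[x$floors$metric == "histogram"]
  )
}

#' @export
autoplot.error_report <- function(object, metric = "hist_pct", ...) {
  fl <- switch(metric,
               hist_pct = object$floors$floor_mean[1L],
               mean_err = object$floors$floor_mean[2L],
               cov_err = object$floors$floor_mean[3L], NULL)
  df <- object$summary
  df$hypothesis <- factor(df$hypothesis, levels = df$hypothesis[order(df[[metric]])])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hypothesis, y = .data[[metric]])) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
  if (!is.null(fl)) p <- p + ggplot2::geom_hline(yintercept = fl, linetype = 2)
  p
}
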