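#' Selection configuration
#'
#' Parameters of the stable-block and time-step inclusion rules: the 100-trial
#' boxcar, the 0.5 normalized thresholds on smoothed acquisition time and its
#' running variance, the 10-trial join gap, the 100-trial minimum block, and
#' the 50-125 mm cursor distance band.
#'
#' @param boxcar Width (trials) of the centered smoothing window.
#' @param learning_threshold Threshold on the normalized smoothed acquisition
#'   time.
#' @param variance_threshold Threshold on the normalized running variance.
#' @param join_gap Maximum separation (trials) between passing runs that are
#'   joined into one block.
#' @param min_block Minimum block length (trials).
#' @param distance_min,distance_max Cursor distance band (mm) from the origin;
#'   the band is half-open: `distance_min` inclusive, `distance_max` exclusive.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(boxcar = 100L, learning_threshold = 0.5,
                             variance_threshold = 0.5, join_gap = 10L,
                             min_block = 100L, distance_min = 50,
                             distance_max = 125) {
  stopifnot(learning_threshold > 0, learning_threshold < 1,
            variance_threshold > 0, variance_threshold < 1,
            min_block >= boxcar, distance_min < distance_max)
  structure(list(boxcar = as.integer(boxcar),
                 learning_threshold = learning_threshold,
                 variance_threshold = variance_threshold,
                 join_gap = as.integer(join_gap),
                 min_block = as.integer(min_block),
                 distance_min = distance_min, distance_max = distance_max),
            class = "selection_config")
}

#' Boxcar-smoothed acquisition times
#'
#' For each trial, the average acquisition time of the *correct* trials inside
#' a `boxcar`-trial window centered on that trial (window `[i - b/2,
#' i + b/2 - 1]`, truncated at the series edges). Trials whose window contains
#' no correct trial get `NA`.
#'
#' @param times Per-trial acquisition times (seconds).
#' @param success Logical per-trial success flags.
#' @param boxcar Window width in trials.
#' @return Numeric vector of smoothed values, one per trial.
#' @export
smooth_acquisition_time <- function(times, success, boxcar = 100L) {
  n <- length(times)
  stopifnot(length(success) == n)
  success <- as.logical(success)
  if (sum(success) < boxcar) {
    stop("fewer correct trials (", sum(success), ") than the ", boxcar,
         "-trial boxcar")
  }
  half <- boxcar %/% 2L
  w <- ifelse(success, times, 0)
  cs <- c(0, cumsum(w))
  cn <- c(0, cumsum(as.numeric(success)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half - 1L, n)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

# centered running variance of a (possibly NA) series in a boxcar window
running_variance <- function(x, boxcar) {
  n <- length(x)
  half <- boxcar %/% 2L
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - half):min(n, i + half - 1L)]
    w <- w[!is.na(w)]
    if (length(w) < 2L) NA_real_ else var(w)
  }, numeric(1))
}

#' Select the stable, learned block of second-mapping trials
#'
#' Implements the full rule chain on the second-mapping trial series: smoothed
#' acquisition times are normalized so 1 is the largest smoothed value in the
#' first 50 trials and 0 the smallest smoothed value in the subsequent trials;
#' the running variance of the smoothed series (100-trial boxcar) is
#' normalized so 1 is the largest variance in the first half of trials and 0
#' the smallest overall. Trials passing both 0.5 thresholds form runs; runs
#' separated by at most `join_gap` trials are joined, and the longest joined
#' run of at least `min_block` trials is returned. If no such block exists the
#' session is excluded.
#'
#' @param times Per-trial acquisition times of the second-mapping trials.
#' @param success Logical success flags.
#' @param cfg A [selection_config()].
#' @return A list of class `stable_block` with `found`, `start`, `end`
#'   (trial indices within the second-mapping series), a `reason` when not
#'   found, and a per-trial `detail` tibble.
#' @export
select_stable_block <- function(times, success, cfg = selection_config()) {
  n <- length(times)
  if (n < 50L) {
    return(no_block("fewer than 50 second-mapping trials"))
  }
  s <- smooth_acquisition_time(times, success, cfg$boxcar)

  M0 <- suppressWarnings(max(s[1:50], na.rm = TRUE))
  m0 <- suppressWarnings(min(s[51:n], na.rm = TRUE))
  if (!is.finite(M0) || !is.finite(m0) || M0 <= m0) {
    return(no_block("degenerate acquisition-time normalization"))
  }
  norm_time <- (s - m0) / (M0 - m0)

  v <- running_variance(s, cfg$boxcar)
  M1 <- suppressWarnings(max(v[seq_len(n %/% 2L)], na.rm = TRUE))
  m1 <- suppressWarnings(min(v, na.rm = TRUE))
  if (!is.finite(M1) || !is.finite(m1) || M1 <= m1) {
    return(no_block("degenerate variance normalization"))
  }
  norm_var <- (v - m1) / (M1 - m1)

  pass <- !is.na(norm_time) & !is.na(norm_var) &
    norm_time < cfg$learning_threshold & norm_var < cfg$variance_threshold

  detail <- tibble::tibble(
    trial = seq_len(n), smoothed = s,
    norm_time = norm_time, norm_var = norm_var, pass = pass
  )

  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0L) {
    return(no_block("no trials pass both thresholds", detail))
  }
  # join runs separated by <= join_gap failing trials
  joined <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      last <- nrow(joined)
      if (runs$start[i] - joined$end[last] - 1L <= cfg$join_gap) {
        joined$end[last] <- runs$end[i]
      } else {
        joined <- rbind(joined, runs[i, ])
      }
    }
  }
  joined$len <- joined$end - joined$start + 1L
  best <- which.max(joined$len)
  if (joined$len[best] < cfg$min_block) {
    return(no_block("longest block shorter than min_block", detail))
  }
  structure(list(found = TRUE, start = joined$start[best],
                 end = joined$end[best], reason = NULL, detail = detail),
            class = "stable_block")
}

no_block <- function(reason, detail = NULL) {
  structure(list(found = FALSE, start = NA_integer_, end = NA_integer_,
                 reason = reason, detail = detail),
            class = "stable_block")
}

#' @export
print.stable_block <- function(x, ...) {
  if (x$found) {
    cat("Stable block: trials", x$start, "-", x$end,
        "(", x$end - x$start + 1L, "trials )\n")
  } else {
    cat("No stable block:", x$reason, "\n")
  }
  invisible(x)
}

#' Time-step inclusion mask for a simulated or loaded session
#'
#' Keeps the time steps that enter the analyses: steps of successful trials,
#' after the cursor freeze, with the cursor center at least `distance_min` and
#' strictly less than `distance_max` mm from the origin, and (for the
#' second-mapping side) inside the selected stable block.
#'
#' @param session A `bci_session` (see [simulate_session()]).
#' @param mapping Which mapping's steps to filter (1 or 2).
#' @param block A [select_stable_block()] result applied to the
#'   second-mapping trials, or `NULL` to apply no block restriction (the
#'   convention for first-mapping activity).
#' @param cfg A [selection_config()].
#' @return Logical vector over all rows of `session$steps`.
#' @export
filter_timesteps <- function(session, mapping = 2L, block = NULL,
                             cfg = selection_config()) {
  st <- session$steps
  tr <- session$trials
  keep_trial <- tr$success & tr$mapping == mapping
  if (!is.null(block)) {
    stopifnot(inherits(block, "stable_block"))
    if (!block$found) return(rep(FALSE, nrow(st)))
    idx_m <- which(tr$mapping == mapping)
    in_block <- rep(FALSE, nrow(tr))
    in_block[idx_m[seq(block$start, block$end)]] <- TRUE
    keep_trial <- keep_trial & in_block
  }
  dist <- sqrt(st$pos_x^2 + st$pos_y^2)
  keep_trial[st$trial] & !st$frozen &
    dist >= cfg$distance_min & dist < cfg$distance_max
}
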