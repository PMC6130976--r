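# Orchestration and serialized session I/O.

mapping_to_list <- function(m) {
  list(A = m$A, B = m$B, c = m$c)
}

fa_to_list <- function(fa) {
  list(L = fa$L, psi = fa$psi, d = fa$d, k = fa$k, n_obs = fa$n_obs,
       loglik_final = tail(fa$loglik, 1L), converged = fa$converged)
}

#' Write a session to disk
#'
#' One delimited counts table (rows = bins, columns = units `u1..uq`), one
#' trial table, one step table, and a JSON sidecar holding the mappings, the
#' factor model, and the configuration/seed. Column order is fixed as
#' written.
#'
#' @param session A `bci_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cts <- as.data.frame(session$counts)
  names(cts) <- paste0("u", seq_len(ncol(cts)))
  utils::write.csv(cts, file.path(dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(session$trials),
                   file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(session$steps),
                   file.path(dir, "steps.csv"), row.names = FALSE)
  sidecar <- list(
    config = unclass(session$config),
    mappings = lapply(session$mappings, mapping_to_list),
    fa = fa_to_list(session$fa),
    clip_fraction = session$clip_fraction
  )
  jsonlite::write_json(sidecar, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' Load a serialized session
#'
#' Round-trips [write_session()] output and validates the schema: counts
#' must be non-negative integers and the tables must carry the documented
#' columns (a missing column is reported by name). The ground-truth object
#' is not serialized; the loaded session carries everything the analysis
#' stages need.
#'
#' @param dir Directory written by [write_session()].
#' @return A `bci_session` (without `ground_truth`).
#' @export
load_session <- function(dir) {
  counts <- as.matrix(utils::read.csv(file.path(dir, "counts.csv")))
  if (any(counts < 0)) stop("counts file contains negative entries")
  if (any(counts != round(counts))) stop("counts file contains non-integer entries")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- NULL

  trials <- tibble::as_tibble(utils::read.csv(file.path(dir, "trials.csv")))
  need_tr <- c("trial", "mapping", "target_deg", "success", "acq_time", "n_bins")
  miss <- setdiff(need_tr, names(trials))
  if (length(miss)) stop("trial table missing column(s): ",
                         paste(miss, collapse = ", "))
  trials$success <- as.logical(trials$success)

  steps <- tibble::as_tibble(utils::read.csv(file.path(dir, "steps.csv")))
  need_st <- c("t", "trial", "bin", "mapping", "frozen", "pos_x", "pos_y",
               "v_x", "v_y", "v_prev_x", "v_prev_y", "theta")
  miss <- setdiff(need_st, names(steps))
  if (length(miss)) stop("step table missing column(s): ",
                         paste(miss, collapse = ", "))
  steps$frozen <- as.logical(steps$frozen)

  side <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  maps <- lapply(side$mappings, function(m) {
    bci_mapping(m$A, m$B, m$c)
  })
  fa_raw <- side$fa
  L <- matrix(fa_raw$L, ncol = fa_raw$k)
  sv <- svd(L)
  sgn <- apply(sv$u, 2L, first_nonzero_sign)
  fa <- structure(list(
    L = L, psi = unlist(fa_raw$psi), d = unlist(fa_raw$d),
    orth_U = sweep(sv$u, 2L, sgn, `*`), orth_S = sv$d,
    orth_V = sweep(sv$v, 2L, sgn, `*`),
    k = fa_raw$k, n_obs = fa_raw$n_obs,
    loglik = fa_raw$loglik_final, converged = fa_raw$converged,
    n_iter = NA_integer_
  ), class = "fa_model")

  cfg <- side$config
  class(cfg) <- "sim_config"
  structure(list(counts = counts, steps = steps, trials = trials,
                 mappings = maps, fa = fa, ground_truth = NULL,
                 frame = NULL, calibration_counts = NULL,
                 clip_fraction = side$clip_fraction, config = cfg),
            class = "bci_session")
}

#' Run the full analysis pipeline on one simulated session
#'
#' Simulate (or reuse) a session, select the stable second-mapping block,
#' run the requested output-null hypotheses, score them against the observed
#' activity with split-half floors, and compute the subspace variance-ratio
#' analysis for the data and for each hypothesis's predictions. When `outdir`
#' is given, every artifact (session tables, per-hypothesis predictions,
#' error and variance tables, and a manifest with the seeds) is written
#' there as CSV/JSON.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory, or `NULL` to skip writing.
#' @param hypotheses Hypotheses to run (default all six).
#' @param direction `"forward"` or `"reverse"`.
#' @param session Optionally a prebuilt `bci_session` (skips simulation).
#' @param hyp_cfg A [hypothesis_config()].
#' @param sel A [selection_config()].
#' @param n_floor_reps Split-half repetitions for the error floor.
#' @return A list of class `pipeline_result` with the session, context,
#'   predictions, `error_report`, and variance-ratio tibble.
#' @export
run_pipeline <- function(config, outdir = NULL,
                         hypotheses = hypothesis_names(),
                         direction = "forward", session = NULL,
                         hyp_cfg = hypothesis_config(seed = config$seed),
                         sel = selection_config(), n_floor_reps = 100L) {
  hypotheses <- match.arg(hypotheses, hypothesis_names(), several.ok = TRUE)
  if (is.null(session)) {
    gt <- make_ground_truth(config)
    session <- simulate_session(gt, config)
  }
  ctx <- prediction_context(session, direction = direction, sel = sel)
  preds <- lapply(hypotheses, function(hy) run_hypothesis(ctx, hy, cfg = hyp_cfg))
  names(preds) <- hypotheses
  report <- evaluate_predictions(ctx, preds, n_floor_reps = n_floor_reps,
                                 seed = config$seed, bin_s = config$bin_s)

  # variance in the dimensions that switched potency
  m_src <- if (direction == "forward") session$mappings[[1L]] else session$mappings[[2L]]
  S <- overlap_subspace(m_src, ctx$map_eval)
  Z1 <- ctx$Z[ctx$idx_src, , drop = FALSE]
  Z2 <- ctx$Z[ctx$idx_eval, , drop = FALSE]
  vr <- list(data = variance_ratio(Z1, Z2, S, ctx$map_eval))
  for (hy in hypotheses) {
    vr[[hy]] <- tryCatch(
      variance_ratio(Z1, recombine_predictions(preds[[hy]], ctx), S, ctx$map_eval),
      error = function(e) NULL)
  }
  vr_tbl <- dplyr::bind_rows(lapply(names(vr), function(g) {
    if (is.null(vr[[g]])) return(NULL)
    dplyr::mutate(vr[[g]]$directions, group = g, average = vr[[g]]$average)
  }))

  out <- structure(list(session = session, context = ctx, predictions = preds,
                        report = report, variance = vr_tbl,
                        config = config, direction = direction),
                   class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline(out, outdir)
  out
}

write_pipeline <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_session(out$session, file.path(outdir, "session"))
  for (hy in names(out$predictions)) {
    utils::write.csv(as.data.frame(tidy(out$predictions[[hy]])),
                     file.path(outdir, paste0("predictions_", hy, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(as.data.frame(out$report$summary),
                   file.path(outdir, "errors.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(out$report$floors),
                   file.path(outdir, "floors.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(out$variance),
                   file.path(outdir, "variance_ratio.csv"), row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("bcinull")),
    seed = out$config$seed, world = out$config$world,
    direction = out$direction,
    hypotheses = names(out$predictions),
    h_bin_width = out$report$h,
    stable_block = c(out$context$block$start, out$context$block$end),
    n_eval_steps = length(out$context$idx_eval),
    n_candidate_steps = length(out$context$idx_src)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report)
  cat("\nVariance ratios (session averages):\n")
  v <- unique(x$variance[, c("group", "average")])
  print(as.data.frame(v), digits = 3)
  invisible(x)
}
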