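#' Run the full closed-loop analysis for one condition
#'
#' Simulates trajectories for a named condition preset (or an explicit
#' [sim_config()]), then runs both bound-fraction estimators side by side:
#' the jump-length two-state fit on tracks of >= 3 frames (the primary
#' estimator) and the MSD log-D mixture on tracks of >= 6 frames. All
#' filter counts are recorded for auditability.
#'
#' @param preset_or_config a preset name for [condition_preset()] or a
#'   `sim_config`.
#' @param seed integer seed driving simulation, fitting starts and
#'   bootstrap.
#' @param n_molecules molecules to simulate (default 5000; ignored when an
#'   explicit config is given).
#' @param n_boot bootstrap replicates for the mixture SEs (0 to skip;
#'   default 100).
#' @param n_timepoints,jumps_to_consider,max_jump,bin_width jump compilation
#'   settings, see [compile_jumps()].
#' @param n_iterations random starts of the two-state fit.
#' @param msd_min_len minimum track length for the MSD path (default 6).
#' @return An object of class `spt_condition_report` containing the config,
#'   `counts` (tracks at each filter), `jump_fit` (an `spt_twostate` or
#'   `NULL` with `jump_error`), `mixture` (an `spt_mixture` or `NULL` with
#'   `mixture_error`), and the settings snapshot.
#' @export
run_condition <- function(preset_or_config, seed = 1, n_molecules = 5000,
                          n_boot = 100, n_timepoints = 6,
                          jumps_to_consider = 4, max_jump = 1.2,
                          bin_width = 0.01, n_iterations = 3,
                          msd_min_len = 6) {
  if (is.character(preset_or_config)) {
    cfg <- condition_preset(preset_or_config, n_molecules = n_molecules,
                            seed = seed)
  } else {
    stopifnot(inherits(preset_or_config, "sim_config"))
    cfg <- preset_or_config
    cfg$seed <- as.integer(seed)
  }
  trajs <- simulate_trajectories(cfg)
  n_sim <- length(trajs$tracks)
  len <- track_lengths(trajs)
  counts <- list(
    simulated = n_sim,
    discarded_short = trajs$provenance$n_discarded_short,
    len_ge_3 = sum(len >= 3),
    len_ge_msd = sum(len >= msd_min_len)
  )

  jump_fit <- NULL
  jump_error <- NULL
  jump_fit <- tryCatch({
    jumps <- compile_jumps(trajs, n_timepoints = n_timepoints,
                           jumps_to_consider = jumps_to_consider,
                           max_jump = max_jump, bin_width = bin_width,
                           min_len = 3)
    fit_two_state(jumps, n_iterations = n_iterations,
                  seed = seed + 1L, dz = cfg$dz)
  }, error = function(e) {
    jump_error <<- conditionMessage(e)
    NULL
  })

  mixture <- NULL
  mixture_error <- NULL
  est <- NULL
  mixture <- tryCatch({
    est <- estimate_diffusion(trajs, min_len = msd_min_len)
    ld <- log_d_distribution(est, quiet = TRUE)
    if (n_boot > 0) {
      bootstrap_mixture(ld, n_boot = n_boot, seed = seed + 2L)
    } else {
      fit_mixture(ld)
    }
  }, error = function(e) {
    mixture_error <<- conditionMessage(e)
    NULL
  })
  if (!is.null(est) && nrow(est) > 0) {
    counts$msd_accepted <- sum(est$accepted)
  } else {
    counts$msd_accepted <- 0L
  }

  structure(
    list(
      condition_label = if (!is.null(cfg$condition)) cfg$condition else
        trajs$condition_label,
      seed = as.integer(seed),
      config = cfg,
      counts = counts,
      jump_fit = jump_fit, jump_error = jump_error,
      mixture = mixture, mixture_error = mixture_error,
      settings = list(n_timepoints = n_timepoints,
                      jumps_to_consider = jumps_to_consider,
                      max_jump = max_jump, bin_width = bin_width,
                      n_iterations = n_iterations, n_boot = n_boot,
                      msd_min_len = msd_min_len)
    ),
    class = "spt_condition_report"
  )
}

#' @export
print.spt_condition_report <- function(x, ...) {
  cat(sprintf("Condition report: %s (seed %d)\n",
              if (is.na(x$condition_label)) "<custom config>" else
                x$condition_label, x$seed))
  cat(sprintf("  tracks: %d simulated, %d >=3 frames, %d >=%d frames, %d MSD-accepted\n",
              x$counts$simulated, x$counts$len_ge_3, x$counts$len_ge_msd,
              x$settings$msd_min_len, x$counts$msd_accepted))
  if (!is.null(x$jump_fit)) {
    p <- x$jump_fit$params
    cat(sprintf("  jump-kinetics bound fraction: %.1f%% (D_free %.2f um^2/s)\n",
                100 * p$f_bound, p$d_free))
  } else {
    cat(sprintf("  jump-kinetics fit FAILED: %s\n", x$jump_error))
  }
  if (!is.null(x$mixture)) {
    cat(sprintf("  MSD-mixture slow weight: %.1f%%\n",
                100 * x$mixture$weights[1]))
  } else {
    cat(sprintf("  MSD-mixture fit FAILED: %s\n", x$mixture_error))
  }
  invisible(x)
}

#' Serializable summary of a condition report
#'
#' @param report an `spt_condition_report`.
#' @return A plain list suitable for `jsonlite::write_json()`.
#' @export
report_to_list <- function(report) {
  stopifnot(inherits(report, "spt_condition_report"))
  cfg <- report$config
  out <- list(
    condition = report$condition_label,
    seed = report$seed,
    generative = list(f_bound = cfg$f_bound, d_bound = cfg$d_bound,
                      d_free = cfg$d_free, sigma_loc = cfg$sigma_loc,
                      dt = cfg$dt, dz = cfg$dz,
                      bleach_prob = cfg$bleach_prob,
                      n_molecules = cfg$n_molecules),
    counts = report$counts,
    settings = report$settings
  )
  if (!is.null(report$jump_fit)) {
    f <- report$jump_fit
    out$jump_fit <- list(
      f_bound = f$params$f_bound, d_bound = f$params$d_bound,
      d_free = f$params$d_free, sigma = f$params$sigma,
      se = as.list(f$se), objective = f$objective,
      converged = f$converged, n_jumps = f$n_jumps
    )
  } else {
    out$jump_fit <- list(failed = TRUE, error = report$jump_error)
  }
  if (!is.null(report$mixture)) {
    m <- report$mixture
    out$msd_mixture <- list(
      f_slow = m$weights[1], means = m$means, sds = m$sds,
      se_weights = m$se_weights, se_means = m$se_means, se_sds = m$se_sds,
      n = m$n, n_boot = m$n_boot, converged = m$converged
    )
  } else {
    out$msd_mixture <- list(failed = TRUE, error = report$mixture_error)
  }
  out
}

#' Write a condition report as JSON
#'
#' @param report an `spt_condition_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Tabulate bound fractions across conditions
#'
#' Collects the two bound-fraction estimators (jump-kinetics primary,
#' MSD-mixture secondary) of several condition reports into one table.
#' Reports with a failed estimator are flagged, not dropped.
#'
#' @param reports a list of `spt_condition_report` objects (>= 2).
#' @return A `data.frame` with one row per report: `condition`, `n_tracks`,
#'   `f_bound_jump`, `f_bound_jump_se`, `d_free_jump`, `f_slow_msd`,
#'   `f_slow_msd_se`, `jump_failed`, `msd_failed`.
#' @export
compare_conditions <- function(reports) {
  if (!is.list(reports) || length(reports) < 2 ||
      !all(vapply(reports, inherits, logical(1), "spt_condition_report"))) {
    stop("`reports` must be a list of >= 2 condition reports", call. = FALSE)
  }
  dts <- vapply(reports, function(r) r$config$dt, numeric(1))
  if (length(unique(dts)) != 1) {
    stop("reports have mixed frame intervals (dt); not comparable",
         call. = FALSE)
  }
  rows <- lapply(reports, function(r) {
    jf <- r$jump_fit
    mx <- r$mixture
    data.frame(
      condition = if (is.na(r$condition_label)) "<custom>" else r$condition_label,
      n_tracks = r$counts$simulated,
      f_bound_jump = if (!is.null(jf)) jf$params$f_bound else NA_real_,
      f_bound_jump_se = if (!is.null(jf)) unname(jf$se["f_bound"]) else NA_real_,
      d_free_jump = if (!is.null(jf)) jf$params$d_free else NA_real_,
      f_slow_msd = if (!is.null(mx)) mx$weights[1] else NA_real_,
      f_slow_msd_se = if (!is.null(mx)) mx$se_weights[1] else NA_real_,
      jump_failed = is.null(jf),
      msd_failed = is.null(mx),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
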