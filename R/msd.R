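#' Time-averaged mean squared displacement of one trajectory
#'
#' Computes, for each lag `n = 1..max_lag` (in frames), the mean over all
#' overlapping pairs `i` of `(x[i+n]-x[i])^2 + (y[i+n]-y[i])^2`.
#'
#' @param traj a trajectory: numeric matrix with columns `frame`, `x`, `y`,
#'   gapless, of length at least `max_lag + 1`.
#' @param max_lag largest lag in frames (default 5, for a linear fit over
#'   lags 2-5).
#' @return A list of class `msd_curve` with `lags` (frames), `msd` (um^2)
#'   and `n_pairs` (pairs averaged per lag).
#' @export
compute_msd <- function(traj, max_lag = 5) {
  if (!is.matrix(traj) || ncol(traj) < 3L) {
    stop("`traj` must be a matrix with columns frame, x, y", call. = FALSE)
  }
  check_number(max_lag, "max_lag", lower = 1, integer = TRUE)
  L <- nrow(traj)
  if (L < max_lag + 1L) {
    stop(sprintf("trajectory has %d frames; need at least max_lag + 1 = %d",
                 L, max_lag + 1L), call. = FALSE)
  }
  if (any(diff(traj[, 1L]) != 1)) {
    stop("trajectory must be gapless (consecutive frames)", call. = FALSE)
  }
  x <- traj[, 2L]
  y <- traj[, 3L]
  msd <- numeric(max_lag)
  n_pairs <- integer(max_lag)
  for (n in seq_len(max_lag)) {
    dx <- x[(n + 1L):L] - x[1L:(L - n)]
    dy <- y[(n + 1L):L] - y[1L:(L - n)]
    msd[n] <- mean(dx^2 + dy^2)
    n_pairs[n] <- L - n
  }
  structure(list(lags = seq_len(max_lag), msd = msd, n_pairs = n_pairs),
            class = "msd_curve")
}

#' Per-trajectory diffusion coefficient from an MSD curve
#'
#' Ordinary least squares of MSD against lag time over lags `{2,3,4,5} * dt`
#' with a free intercept; the slope divided by 4 (the 2D Brownian prefactor)
#' gives D. The free intercept absorbs the `4 sigma^2` localization-error
#' offset, so D needs no explicit error subtraction. A track is accepted
#' when the fit has `R^2 > 0.8` and a positive slope (log D undefined
#' otherwise).
#'
#' @param curve an [compute_msd()] result containing lags 2-5.
#' @param dt frame interval, seconds.
#' @param track_id optional id carried through to the result.
#' @return A list of class `diffusion_estimate` with `d` (um^2/s),
#'   `r_squared`, `accepted` and `log10_d` (`NA` when not accepted).
#' @export
estimate_d <- function(curve, dt, track_id = NA_character_) {
  stopifnot(inherits(curve, "msd_curve"))
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  fit_lags <- 2:5
  if (!all(fit_lags %in% curve$lags)) {
    stop("MSD curve must contain lags 2..5 (at least 4 lag points)",
         call. = FALSE)
  }
  tau <- fit_lags * dt
  msd <- curve$msd[match(fit_lags, curve$lags)]
  mx <- mean(tau)
  my <- mean(msd)
  sxx <- sum((tau - mx)^2)
  sxy <- sum((tau - mx) * (msd - my))
  slope <- sxy / sxx
  syy <- sum((msd - my)^2)
  r2 <- if (syy > 0) (sxy^2 / (sxx * syy)) else 0
  d <- slope / 4
  accepted <- is.finite(r2) && r2 > 0.8 && slope > 0
  structure(
    list(track_id = track_id, d = d, r_squared = r2, accepted = accepted,
         log10_d = if (accepted) log10(d) else NA_real_),
    class = "diffusion_estimate"
  )
}

#' Diffusion estimates for all sufficiently long tracks of a set
#'
#' Applies the MSD pipeline (tracks of at least `min_len` frames, MSD over
#' lags 1..5, linear fit over lags 2-5, `R^2 > 0.8` acceptance) to a whole
#' trajectory set.
#'
#' @param trajs a [trajectory_set()].
#' @param min_len minimum track length in frames (default 6).
#' @param max_lag largest MSD lag (default 5).
#' @return A `data.frame` with one row per analyzed track: `track_id`,
#'   `d_um2s`, `r2`, `accepted`, `log10_d`.
#' @export
estimate_diffusion <- function(trajs, min_len = 6, max_lag = 5) {
  stopifnot(inherits(trajs, "trajectory_set"))
  keep <- filter_min_length(trajs, min_len, quiet = TRUE)
  ids <- names(keep$tracks)
  n <- length(ids)
  d <- numeric(n); r2 <- numeric(n); acc <- logical(n); ld <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    est <- estimate_d(compute_msd(keep$tracks[[j]], max_lag = max_lag),
                      dt = trajs$dt, track_id = ids[j])
    d[j] <- est$d; r2[j] <- est$r_squared
    acc[j] <- est$accepted; ld[j] <- est$log10_d
  }
  data.frame(track_id = ids, d_um2s = d, r2 = r2, accepted = acc,
             log10_d = ld, stringsAsFactors = FALSE)
}

#' Accepted log10 diffusion coefficients
#'
#' Extracts `log10(D)` of accepted tracks (positive slope, `R^2 > 0.8`) from
#' a table of per-track estimates, reporting the rejection count. Warns when
#' fewer than 1000 accepted tracks remain, below the regime the analysis is
#' designed for.
#'
#' @param estimates the `data.frame` returned by [estimate_diffusion()], or
#'   a list of [estimate_d()] results.
#' @param quiet suppress the count message.
#' @return Numeric vector of accepted `log10(D)` values, with the number of
#'   rejected tracks in `attr(, "n_rejected")`.
#' @export
log_d_distribution <- function(estimates, quiet = FALSE) {
  if (is.list(estimates) && !is.data.frame(estimates)) {
    estimates <- do.call(rbind, lapply(estimates, function(e) {
      data.frame(track_id = e$track_id, d_um2s = e$d, r2 = e$r_squared,
                 accepted = e$accepted, log10_d = e$log10_d,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(estimates) || nrow(estimates) == 0) {
    stop("no diffusion estimates supplied", call. = FALSE)
  }
  acc <- estimates$accepted
  if (!any(acc)) stop("all tracks rejected by the MSD fit filter", call. = FALSE)
  out <- estimates$log10_d[acc]
  if (!quiet) {
    message(sprintf("log_d_distribution: %d accepted, %d rejected tracks",
                    sum(acc), sum(!acc)))
  }
  if (sum(acc) <= 1000) {
    warning(sprintf(
      "only %d accepted tracks; the analysis regime assumes n > 1000",
      sum(acc)), call. = FALSE)
  }
  attr(out, "n_rejected") <- sum(!acc)
  out
}
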