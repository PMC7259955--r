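#' Simulate two-state single-particle trajectories
#'
#' Generates observed trajectories under the generative counterpart of the
#' two-state kinetic model. Each molecule is assigned a state once for its
#' whole lifetime: chromatin-bound with probability `f_bound` (diffusing
#' slowly at `d_bound`) or free (diffusing at `d_free`). True lateral
#' positions evolve as 2D Brownian motion with per-axis per-frame
#' displacement SD `sqrt(2 * D * dt)`; observed positions add independent
#' Gaussian localization noise with SD `sigma_loc` per axis.
#'
#' Free molecules additionally diffuse axially (same D) inside the detection
#' slab of thickness `dz`, starting from a uniform axial position; the track
#' terminates when the molecule leaves the slab. Axial motion is propagated
#' in 10 sub-steps per frame with Brownian-bridge boundary-crossing tests, so
#' that termination follows the continuous absorbing-slab law that the
#' analytic [z_correction()] describes. Bound molecules are held in focus.
#' All tracks also terminate by photobleaching (geometric lifetime with rate
#' `bleach_prob` per frame) and at the end of the movie. Tracks shorter than
#' `min_track_len` frames are dropped.
#'
#' @param config a [sim_config()].
#' @return A [trajectory_set()] whose `provenance` records the generative
#'   config plus per-track ground truth: `state` ("bound"/"free") and
#'   `end_reason` ("bleach", "z_exit" or "movie_end"), both named by track
#'   id, and `n_discarded_short`, the number of tracks dropped by the
#'   minimum-length filter.
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_impl(config))
}

.simulate_impl <- function(config) {
  n <- config$n_molecules
  bound <- stats::runif(n) < config$f_bound

  # Photobleaching: geometric number of observed frames (support >= 1).
  if (config$bleach_prob > 0) {
    life_bleach <- 1L + stats::rgeom(n, config$bleach_prob)
  } else {
    life_bleach <- rep(.Machine$integer.max, n)
  }

  start <- if (config$stagger_starts) {
    sample.int(config$n_frames, n, replace = TRUE)
  } else {
    rep(1L, n)
  }
  cap <- config$n_frames - start + 1L
  life <- pmin(life_bleach, cap)

  # Axial survival of free molecules: number of frames observed before the
  # molecule first leaves the slab [0, dz].
  life_z <- rep(.Machine$integer.max, n)
  free_idx <- which(!bound)
  if (length(free_idx) > 0 && config$d_free > 0) {
    life_z[free_idx] <- .slab_survival_frames(
      n = length(free_idx), d = config$d_free, dt = config$dt,
      dz = config$dz, max_frames = life[free_idx], n_sub = 10L
    )
  }
  end_reason <- ifelse(!bound & life_z < life, "z_exit",
                       ifelse(life_bleach <= cap, "bleach", "movie_end"))
  life <- pmin(life, life_z)

  keep <- life >= config$min_track_len
  n_short <- sum(!keep)
  idx <- which(keep)
  tracks <- vector("list", length(idx))
  if (length(idx) > 0) {
    L <- life[idx]
    d_mol <- ifelse(bound[idx], config$d_bound, config$d_free)
    step_sd <- sqrt(2 * d_mol * config$dt)
    total <- sum(L)
    mol_of <- rep.int(seq_along(idx), L)
    first <- c(TRUE, diff(mol_of) != 0L)

    sd_vec <- step_sd[mol_of]
    sd_vec[first] <- 0 # no increment into the first frame
    dx <- stats::rnorm(total, 0, sd_vec)
    dy <- stats::rnorm(total, 0, sd_vec)
    x0 <- stats::runif(length(idx), 0, config$roi)
    y0 <- stats::runif(length(idx), 0, config$roi)
    dx[first] <- x0
    dy[first] <- y0
    # cumulative sums restarted at each molecule
    xs <- cumsum(dx)
    ys <- cumsum(dy)
    off_x <- xs[first] - x0
    off_y <- ys[first] - y0
    xs <- xs - off_x[mol_of]
    ys <- ys - off_y[mol_of]
    if (config$sigma_loc > 0) {
      xs <- xs + stats::rnorm(total, 0, config$sigma_loc)
      ys <- ys + stats::rnorm(total, 0, config$sigma_loc)
    }
    frames <- (start[idx][mol_of]) + (seq_len(total) -
      rep.int(cumsum(c(0L, L[-length(L)])) + 1L, L))

    ends <- cumsum(L)
    begins <- ends - L + 1L
    for (j in seq_along(idx)) {
      rng <- begins[j]:ends[j]
      tracks[[j]] <- cbind(frame = frames[rng], x = xs[rng], y = ys[rng])
    }
  }
  ids <- sprintf("t%05d", idx)
  names(tracks) <- ids
  state <- ifelse(bound[idx], "bound", "free")
  names(state) <- ids
  er <- end_reason[idx]
  names(er) <- ids

  trajectory_set(
    tracks, dt = config$dt,
    condition_label = if (!is.null(config$condition)) config$condition else NA_character_,
    provenance = list(
      config = config, state = state, end_reason = er,
      n_discarded_short = n_short
    )
  )
}

# For `n` molecules starting uniform in [0, dz], return the number of frames
# observed in-slab before first boundary crossing (continuous absorption via
# sub-steps + Brownian-bridge crossing tests). `max_frames[i]` caps molecule
# i; molecules still alive at their cap stop being propagated. Vectorized
# over molecules.
.slab_survival_frames <- function(n, d, dt, dz, max_frames, n_sub = 10L) {
  h <- dt / n_sub
  sd_sub <- sqrt(2 * d * h)
  z <- stats::runif(n, 0, dz)
  transitions <- rep(0L, n) # completed frame-to-frame survivals
  active <- which(max_frames > 1L)
  while (length(active) > 0) {
    za <- z[active]
    dead <- rep(FALSE, length(active))
    for (s in seq_len(n_sub)) {
      znew <- za + stats::rnorm(length(za), 0, sd_sub)
      crossed <- znew < 0 | znew > dz
      # Brownian-bridge excursion beyond either boundary between sub-steps
      not_crossed <- which(!crossed & !dead)
      if (length(not_crossed) > 0) {
        z0 <- za[not_crossed]
        z1 <- znew[not_crossed]
        p_lo <- exp(-z0 * z1 / (d * h))
        p_hi <- exp(-(dz - z0) * (dz - z1) / (d * h))
        p <- p_lo + p_hi - p_lo * p_hi
        crossed[not_crossed] <- stats::runif(length(not_crossed)) < p
      }
      dead <- dead | crossed
      za <- znew
    }
    surv <- active[!dead]
    transitions[surv] <- transitions[surv] + 1L
    z[active] <- za
    active <- surv[transitions[surv] < max_frames[surv] - 1L]
  }
  1L + transitions
}

#' Simulate per-frame localizations
#'
#' Runs [simulate_trajectories()] and emits the observed positions of all
#' concurrently active molecules frame by frame, unlabeled by identity, for
#' testing the linking stage against known ground truth.
#'
#' @param config a [sim_config()].
#' @return A `data.frame` with columns `frame`, `x`, `y` (um), sorted by
#'   frame (ties by x), of class `localization_table`. The ground-truth
#'   molecule id of every row is kept in `attr(, "truth_id")`, and the
#'   originating `trajectory_set` in `attr(, "truth_tracks")`.
#' @export
simulate_localizations <- function(config) {
  trajs <- simulate_trajectories(config)
  n <- track_lengths(trajs)
  df <- data.frame(
    frame = unlist(lapply(trajs$tracks, function(m) as.integer(m[, "frame"])),
                   use.names = FALSE),
    x = unlist(lapply(trajs$tracks, function(m) m[, "x"]), use.names = FALSE),
    y = unlist(lapply(trajs$tracks, function(m) m[, "y"]), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  truth <- rep(names(trajs$tracks), n)
  ord <- order(df$frame, df$x, df$y)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "truth_id") <- truth[ord]
  attr(df, "truth_tracks") <- trajs
  class(df) <- c("localization_table", "data.frame")
  df
}

#' Read and write localization tables
#'
#' Localization CSVs have a header and columns `frame,x_um,y_um`.
#'
#' @param locs a localization table (`data.frame` with `frame`, `x`, `y`).
#' @param path file path.
#' @return `read_localizations()` returns a `localization_table`;
#'   `write_localizations()` returns `path` invisibly.
#' @export
write_localizations <- function(locs, path) {
  df <- data.frame(frame = as.integer(locs$frame),
                   x_um = signif(locs$x, 8), y_um = signif(locs$y, 8))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop(sprintf("localization CSV must have columns %s",
                 paste(need, collapse = ",")), call. = FALSE)
  }
  if (any(df$frame < 0)) stop("negative frame indices", call. = FALSE)
  out <- data.frame(frame = as.integer(df$frame), x = df$x_um, y = df$y_um)
  out <- out[order(out$frame, out$x, out$y), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("localization_table", "data.frame")
  out
}
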