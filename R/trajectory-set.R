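#' Trajectory set container
#'
#' A `trajectory_set` holds single-molecule trajectories sharing one frame
#' interval `dt`. Each trajectory is a numeric matrix with columns `frame`,
#' `x`, `y` (positions in um), at least two rows, and consecutive frame
#' indices (gapless, strictly increasing by 1).
#'
#' @param tracks named list of numeric matrices with columns `frame`, `x`,
#'   `y`; names are the track ids and must be unique.
#' @param dt frame interval in seconds, shared by all trajectories.
#' @param condition_label optional free-text label for the condition.
#' @param provenance optional list of metadata (e.g. generative parameters,
#'   ground-truth states).
#'
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(tracks, dt, condition_label = NA_character_,
                           provenance = list()) {
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  if (!is.list(tracks)) stop("`tracks` must be a list of matrices", call. = FALSE)
  if (length(tracks) > 0) {
    if (is.null(names(tracks)) || anyDuplicated(names(tracks)) ||
        any(!nzchar(names(tracks)))) {
      stop("track ids (names of `tracks`) must be unique and non-empty",
           call. = FALSE)
    }
    for (id in names(tracks)) {
      m <- tracks[[id]]
      if (!is.matrix(m) || !is.numeric(m) || ncol(m) != 3L) {
        stop(sprintf("track %s: must be a numeric matrix with columns frame, x, y",
                     dQuote(id)), call. = FALSE)
      }
      if (nrow(m) < 2L) {
        stop(sprintf("track %s: a trajectory needs at least 2 frames",
                     dQuote(id)), call. = FALSE)
      }
      fr <- m[, 1L]
      if (any(diff(fr) != 1)) {
        stop(sprintf("track %s: frames must be consecutive (gapless, step 1)",
                     dQuote(id)), call. = FALSE)
      }
      colnames(tracks[[id]]) <- c("frame", "x", "y")
    }
  }
  structure(
    list(tracks = tracks, dt = dt, condition_label = condition_label,
         provenance = provenance),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  n <- length(x$tracks)
  cat(sprintf("Trajectory set: %d tracks, dt = %g s", n, x$dt))
  if (!is.na(x$condition_label)) cat(sprintf("  [%s]", x$condition_label))
  cat("\n")
  if (n > 0) {
    len <- track_lengths(x)
    cat(sprintf("  track length (frames): min %d, median %g, max %d\n",
                min(len), stats::median(len), max(len)))
  }
  invisible(x)
}

#' @export
length.trajectory_set <- function(x) length(x$tracks)

#' Track lengths of a trajectory set
#'
#' @param trajs a [trajectory_set()].
#' @return Integer vector of per-track lengths (number of frames), named by
#'   track id.
#' @export
track_lengths <- function(trajs) {
  stopifnot(inherits(trajs, "trajectory_set"))
  vapply(trajs$tracks, nrow, integer(1))
}

#' Keep only trajectories of a minimum length
#'
#' Applies the minimum-track-length filter used throughout the analysis
#' (3 frames for jump-length compilation, 6 frames for MSD fitting) and
#' reports how many tracks survive.
#'
#' @param trajs a [trajectory_set()].
#' @param min_len minimum number of frames (>= 2).
#' @param quiet suppress the filter-count message.
#' @return The filtered `trajectory_set`.
#' @export
filter_min_length <- function(trajs, min_len, quiet = FALSE) {
  stopifnot(inherits(trajs, "trajectory_set"))
  check_number(min_len, "min_len", lower = 2, integer = TRUE)
  keep <- track_lengths(trajs) >= min_len
  out <- trajs
  out$tracks <- trajs$tracks[keep]
  if (!is.null(out$provenance$state)) {
    out$provenance$state <- out$provenance$state[names(out$tracks)]
  }
  if (!is.null(out$provenance$end_reason)) {
    out$provenance$end_reason <- out$provenance$end_reason[names(out$tracks)]
  }
  if (!quiet) {
    message(sprintf("filter_min_length(%d): kept %d of %d tracks",
                    min_len, sum(keep), length(keep)))
  }
  out
}

#' Read and write trajectory tables
#'
#' Trajectory CSVs have a header and columns `track_id,frame,x_um,y_um` with
#' positions in um. `write_trajectories()` emits positions with 8 significant
#' digits.
#'
#' @param trajs a [trajectory_set()].
#' @param path file path.
#' @param dt frame interval in seconds to attach on read.
#' @param condition_label optional condition label to attach on read.
#' @return `read_trajectories()` returns a `trajectory_set`;
#'   `write_trajectories()` returns `path` invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  stopifnot(inherits(trajs, "trajectory_set"))
  ids <- names(trajs$tracks)
  n <- track_lengths(trajs)
  df <- data.frame(
    track_id = rep(ids, n),
    frame = unlist(lapply(trajs$tracks, function(m) as.integer(m[, "frame"])),
                   use.names = FALSE),
    x_um = signif(unlist(lapply(trajs$tracks, function(m) m[, "x"]),
                         use.names = FALSE), 8),
    y_um = signif(unlist(lapply(trajs$tracks, function(m) m[, "y"]),
                         use.names = FALSE), 8),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path, dt, condition_label = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop(sprintf("trajectory CSV must have columns %s",
                 paste(need, collapse = ",")), call. = FALSE)
  }
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  tracks <- lapply(split(seq_len(nrow(df)), df$track_id), function(i) {
    cbind(frame = df$frame[i], x = df$x_um[i], y = df$y_um[i])
  })
  trajectory_set(tracks, dt = dt, condition_label = condition_label,
                 provenance = list(source = path))
}
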