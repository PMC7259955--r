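#' Linking configuration
#'
#' Settings for assembling per-frame localizations into trajectories: a hard
#' maximum-jump gate in pixels and the minimum track length to keep. Two
#' documented length profiles are used downstream: 3 frames for jump-length
#' analysis, 6 frames for MSD analysis.
#'
#' @param max_jump_px maximum frame-to-frame jump, pixels (default 5).
#' @param pixel_size pixel size, um (default 0.107).
#' @param min_track_len minimum track length in frames (default 3).
#' @return A list of class `link_config`.
#' @export
link_config <- function(max_jump_px = 5, pixel_size = 0.107,
                        min_track_len = 3) {
  check_number(max_jump_px, "max_jump_px", lower = 0, strict_lower = TRUE)
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(min_track_len, "min_track_len", lower = 2, integer = TRUE)
  structure(list(max_jump_px = max_jump_px, pixel_size = pixel_size,
                 min_track_len = as.integer(min_track_len)),
            class = "link_config")
}

#' Link localizations into trajectories
#'
#' Frame-to-frame tracking: detections in frame `f+1` are assigned to tracks
#' ending in frame `f` by the assignment that, among candidate pairs within
#' the gate radius `max_jump_px * pixel_size`, links as many pairs as
#' possible with minimum total squared displacement (optimal bipartite
#' assignment, solved exactly per connected component of the gated candidate
#' graph). Unmatched detections start new tracks; tracks with no match
#' terminate (no gap closing). Ties in assignment cost are broken by the
#' lexicographic (frame, x, y) order of the earlier detection, making the
#' result deterministic and independent of input row order.
#'
#' @param locs a localization table: `data.frame` with columns `frame`, `x`,
#'   `y` (um), e.g. from [simulate_localizations()] or
#'   [read_localizations()].
#' @param config a [link_config()].
#' @param dt frame interval in seconds for the resulting set (default 0.01).
#' @return A [trajectory_set()]; `provenance$rows` maps each track to the
#'   row indices of the canonically sorted input table. Empty input yields
#'   an empty set.
#' @export
link_localizations <- function(locs, config = link_config(), dt = 0.01) {
  stopifnot(inherits(config, "link_config"))
  if (is.null(locs) || nrow(locs) == 0) {
    return(trajectory_set(structure(list(), names = character(0)), dt = dt,
                          provenance = list(link_config = config)))
  }
  if (!all(c("frame", "x", "y") %in% names(locs))) {
    stop("`locs` must have columns frame, x, y", call. = FALSE)
  }
  if (any(locs$frame < 0)) stop("negative frame indices", call. = FALSE)
  ord <- order(locs$frame, locs$x, locs$y)
  fr <- as.integer(locs$frame[ord])
  px <- locs$x[ord]
  py <- locs$y[ord]
  radius2 <- (config$max_jump_px * config$pixel_size)^2

  by_frame <- split(seq_along(fr), fr)
  frames <- as.integer(names(by_frame))

  tracks_rows <- list()      # closed + open track row-index vectors
  open_idx <- integer(0)     # indices into tracks_rows that are open
  open_frame <- integer(0)   # last frame of each open track

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    rows <- by_frame[[fi]]
    # close tracks not ending at f - 1
    still <- open_frame == f - 1L
    active <- open_idx[still]
    open_idx <- active
    open_frame <- open_frame[still]

    assigned <- rep(NA_integer_, length(rows))
    if (length(active) > 0 && length(rows) > 0) {
      last_row <- vapply(active, function(ti) {
        v <- tracks_rows[[ti]]
        v[length(v)]
      }, integer(1))
      assigned <- .assign_frame(px[last_row], py[last_row],
                                px[rows], py[rows], radius2)
    }
    matched_det <- stats::na.omit(assigned)
    # extend matched tracks
    for (i in seq_along(active)) {
      if (!is.na(assigned[i])) {
        ti <- active[i]
        tracks_rows[[ti]] <- c(tracks_rows[[ti]], rows[assigned[i]])
      }
    }
    keep_open <- !is.na(assigned)
    new_rows <- if (length(rows) > 0) {
      setdiff(seq_along(rows), matched_det)
    } else integer(0)
    # start new tracks for unmatched detections
    new_idx <- integer(length(new_rows))
    for (j in seq_along(new_rows)) {
      tracks_rows[[length(tracks_rows) + 1L]] <- rows[new_rows[j]]
      new_idx[j] <- length(tracks_rows)
    }
    open_idx <- c(active[keep_open], new_idx)
    open_frame <- rep(f, length(open_idx))
  }

  keep <- vapply(tracks_rows, length, integer(1)) >= config$min_track_len
  tracks_rows <- tracks_rows[keep]
  ids <- sprintf("L%05d", seq_along(tracks_rows))
  tracks <- lapply(tracks_rows, function(v) {
    cbind(frame = fr[v], x = px[v], y = py[v])
  })
  names(tracks) <- ids
  n_total <- length(fr)
  n_in_tracks <- sum(vapply(tracks_rows, length, integer(1)))
  message(sprintf(
    "link_localizations: %d tracks from %d detections (%d in tracks, %d orphaned/short)",
    length(tracks), n_total, n_in_tracks, n_total - n_in_tracks))
  rowmap <- tracks_rows
  names(rowmap) <- ids
  trajectory_set(tracks, dt = dt,
                 provenance = list(link_config = config, rows = rowmap))
}

# Optimal gated assignment of m "from" points to n "to" points:
# maximum-cardinality matching of pairs with squared distance <= radius2,
# minimum total squared distance among those; exact per connected component
# (exhaustive search; components are small at SPT densities), deterministic
# greedy fallback for components with > 8 "from" nodes.
# Returns an integer vector of length m with the matched "to" index or NA.
.assign_frame <- function(fx, fy, tx, ty, radius2) {
  m <- length(fx)
  n <- length(tx)
  d2 <- outer(fx, tx, function(a, b) (a - b)^2) +
    outer(fy, ty, function(a, b) (a - b)^2)
  gate <- d2 <= radius2
  out <- rep(NA_integer_, m)
  if (!any(gate)) return(out)

  # connected components over the bipartite gate graph (union-find)
  parent <- seq_len(m + n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(m)) {
    for (j in which(gate[i, ])) {
      ri <- find(i); rj <- find(m + j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots_from <- vapply(seq_len(m), find, integer(1))
  roots_to <- vapply(m + seq_len(n), find, integer(1))
  for (root in unique(roots_from)) {
    ci <- which(roots_from == root)
    cj <- which(roots_to == root)
    if (length(cj) == 0) next
    sub <- .match_component(d2[ci, cj, drop = FALSE], gate[ci, cj, drop = FALSE])
    out[ci] <- ifelse(is.na(sub), NA_integer_, cj[sub])
  }
  out
}

.match_component <- function(d2, gate) {
  m <- nrow(d2)
  n <- ncol(d2)
  if (m == 1L) {
    j <- which(gate[1L, ])
    if (length(j) == 0) return(NA_integer_)
    return(j[which.min(d2[1L, j])])
  }
  if (m > 8L) return(.match_greedy(d2, gate))
  best_assign <- NULL
  best_card <- -1L
  best_cost <- Inf
  assign <- rep(NA_integer_, m)
  used <- rep(FALSE, n)
  recurse <- function(i, card, cost) {
    if (i > m) {
      if (card > best_card ||
          (card == best_card && cost < best_cost - 1e-15)) {
        best_card <<- card
        best_cost <<- cost
        best_assign <<- assign
      }
      return(invisible())
    }
    # bound: even matching everything remaining cannot beat best
    if (card + (m - i + 1L) < best_card) return(invisible())
    cand <- which(gate[i, ] & !used)
    cand <- cand[order(d2[i, cand])]
    for (j in cand) {
      assign[i] <<- j
      used[j] <<- TRUE
      recurse(i + 1L, card + 1L, cost + d2[i, j])
      used[j] <<- FALSE
      assign[i] <<- NA_integer_
    }
    recurse(i + 1L, card, cost)
  }
  recurse(1L, 0L, 0)
  best_assign
}

# Deterministic greedy fallback: accept gated pairs in increasing distance
# order (ties by row then column index).
.match_greedy <- function(d2, gate) {
  m <- nrow(d2)
  idx <- which(gate, arr.ind = TRUE)
  if (nrow(idx) == 0) return(rep(NA_integer_, m))
  ordp <- order(d2[idx], idx[, 1], idx[, 2])
  idx <- idx[ordp, , drop = FALSE]
  out <- rep(NA_integer_, m)
  used <- rep(FALSE, ncol(d2))
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1]; j <- idx[p, 2]
    if (is.na(out[i]) && !used[j]) {
      out[i] <- j
      used[j] <- TRUE
    }
  }
  out
}

#' Fraction of links matching ground truth
#'
#' Scores a linking result against the ground-truth identities retained by
#' [simulate_localizations()]: a link (consecutive pair within a linked
#' track) is correct when both detections belong to the same true molecule.
#' Use a linking run with `min_track_len = 2` so that no true link is
#' discarded by the length filter.
#'
#' @param locs the localization table given to [link_localizations()], with
#'   its `truth_id` attribute.
#' @param linked the resulting [trajectory_set()].
#' @return A list with `accuracy` (correct links / true links), and counts
#'   `n_correct`, `n_links`, `n_true`.
#' @export
link_accuracy <- function(locs, linked) {
  truth <- attr(locs, "truth_id")
  if (is.null(truth)) stop("`locs` carries no truth_id attribute", call. = FALSE)
  ord <- order(locs$frame, locs$x, locs$y)
  truth <- truth[ord]
  rowmap <- linked$provenance$rows
  if (is.null(rowmap)) stop("`linked` carries no provenance$rows", call. = FALSE)
  n_correct <- 0L
  n_links <- 0L
  for (v in rowmap) {
    if (length(v) < 2) next
    a <- truth[v[-length(v)]]
    b <- truth[v[-1]]
    n_links <- n_links + length(a)
    n_correct <- n_correct + sum(a == b)
  }
  n_true <- sum(table(truth) - 1L)
  list(accuracy = if (n_true > 0) n_correct / n_true else NA_real_,
       n_correct = n_correct, n_links = n_links, n_true = as.integer(n_true))
}
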