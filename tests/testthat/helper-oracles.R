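# Independent oracles used across tests.

# Brute-force time-averaged MSD: explicit double loop over all pairs.
msd_brute <- function(traj, max_lag) {
  x <- traj[, 2]; y <- traj[, 3]
  L <- nrow(traj)
  vapply(seq_len(max_lag), function(n) {
    acc <- 0
    for (i in 1:(L - n)) {
      acc <- acc + (x[i + n] - x[i])^2 + (y[i + n] - y[i])^2
    }
    acc / (L - n)
  }, numeric(1))
}

# Monte-Carlo absorbing-slab survival: walkers start uniform in [0, dz],
# diffuse at d for delta_tau with 1 ms sub-steps and Brownian-bridge
# boundary-crossing tests; returns the surviving fraction.
mc_slab_survival <- function(delta_tau, dz, d, n_walkers = 1e5, h = 1e-3) {
  n_steps <- max(1L, round(delta_tau / h))
  h <- delta_tau / n_steps
  z <- stats::runif(n_walkers, 0, dz)
  alive <- rep(TRUE, n_walkers)
  for (s in seq_len(n_steps)) {
    idx <- which(alive)
    if (length(idx) == 0) break
    z1 <- z[idx] + stats::rnorm(length(idx), 0, sqrt(2 * d * h))
    out <- z1 < 0 | z1 > dz
    p_cross <- exp(-pmax(z[idx], 0) * pmax(z1, 0) / (d * h)) +
      exp(-pmax(dz - z[idx], 0) * pmax(dz - z1, 0) / (d * h))
    dead <- out | stats::runif(length(idx)) < p_cross
    alive[idx[dead]] <- FALSE
    z[idx] <- z1
  }
  mean(alive)
}

# Exhaustive minimum-cost maximum-cardinality gated matching over ALL
# partial assignments (no component decomposition): the linking oracle.
match_brute <- function(fx, fy, tx, ty, radius2) {
  m <- length(fx); n <- length(tx)
  d2 <- outer(fx, tx, function(a, b) (a - b)^2) +
    outer(fy, ty, function(a, b) (a - b)^2)
  gate <- d2 <= radius2
  best <- list(card = -1L, cost = Inf, assign = rep(NA_integer_, m))
  assign <- rep(NA_integer_, m)
  used <- rep(FALSE, max(n, 1))
  recur <- function(i, card, cost) {
    if (i > m) {
      if (card > best$card || (card == best$card && cost < best$cost - 1e-15)) {
        best <<- list(card = card, cost = cost, assign = assign)
      }
      return(invisible())
    }
    for (j in seq_len(n)) {
      if (gate[i, j] && !used[j]) {
        assign[i] <<- j; used[j] <<- TRUE
        recur(i + 1L, card + 1L, cost + d2[i, j])
        assign[i] <<- NA_integer_; used[j] <<- FALSE
      }
    }
    recur(i + 1L, card, cost)
  }
  recur(1L, 0L, 0)
  best
}

# Build a trajectory matrix from position vectors (frames 1..n).
make_track <- function(x, y = rep(0, length(x)), start_frame = 1L) {
  cbind(frame = start_frame + seq_along(x) - 1L, x = x, y = y)
}

# Localization table from explicit rows, canonical class and attributes.
make_locs <- function(frame, x, y, truth = NULL) {
  df <- data.frame(frame = as.integer(frame), x = x, y = y)
  ord <- order(df$frame, df$x, df$y)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(truth)) attr(df, "truth_id") <- truth[ord]
  class(df) <- c("localization_table", "data.frame")
  df
}
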