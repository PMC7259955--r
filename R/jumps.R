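#' Compile jump-length distributions over multiple frame intervals
#'
#' For each interval multiple `k = 1..n_timepoints`, collects displacements
#' between positions `k` frames apart from all trajectories of at least
#' `min_len` frames, taking at most `jumps_to_consider` jumps per trajectory
#' per interval (earliest first) and discarding displacements larger than
#' `max_jump`.
#'
#' @param trajs a [trajectory_set()].
#' @param n_timepoints number of interval multiples (default 6, i.e.
#'   10-60 ms at `dt` = 10 ms).
#' @param jumps_to_consider cap on jumps per trajectory per interval
#'   (default 4; the "use entire trajectories: no" convention).
#' @param max_jump largest displacement kept, um (default 1.2).
#' @param bin_width histogram/CDF bin width, um (default 0.01).
#' @param min_len minimum trajectory length in frames (default 3).
#' @return An object of class `spt_jumps`: `jumps` (list of displacement
#'   vectors per interval), `dt`, `settings`, `n_tracks`,
#'   `n_over_max` (discarded long jumps).
#' @export
compile_jumps <- function(trajs, n_timepoints = 6, jumps_to_consider = 4,
                          max_jump = 1.2, bin_width = 0.01, min_len = 3) {
  stopifnot(inherits(trajs, "trajectory_set"))
  check_number(n_timepoints, "n_timepoints", lower = 1, integer = TRUE)
  check_number(jumps_to_consider, "jumps_to_consider", lower = 1, integer = TRUE)
  check_number(max_jump, "max_jump", lower = 0, strict_lower = TRUE)
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  check_number(min_len, "min_len", lower = 2, integer = TRUE)

  keep <- filter_min_length(trajs, min_len, quiet = TRUE)
  if (length(keep$tracks) == 0) {
    stop("no trajectories of sufficient length to compile jumps", call. = FALSE)
  }
  jumps <- vector("list", n_timepoints)
  # count of jumps by (interval k, start age i = 0..J-1); used downstream to
  # weight the axial-survival correction by the observed age composition
  age_counts <- matrix(0L, nrow = n_timepoints, ncol = jumps_to_consider,
                       dimnames = list(NULL, paste0("age", seq_len(jumps_to_consider) - 1L)))
  for (k in seq_len(n_timepoints)) jumps[[k]] <- vector("list", length(keep$tracks))
  for (j in seq_along(keep$tracks)) {
    m <- keep$tracks[[j]]
    L <- nrow(m)
    for (k in seq_len(n_timepoints)) {
      n_avail <- L - k
      if (n_avail < 1L) next
      n_take <- min(jumps_to_consider, n_avail)
      take <- seq_len(n_take)
      dx <- m[take + k, 2L] - m[take, 2L]
      dy <- m[take + k, 3L] - m[take, 3L]
      jumps[[k]][[j]] <- sqrt(dx * dx + dy * dy)
      age_counts[k, take] <- age_counts[k, take] + 1L
    }
  }
  n_over <- 0L
  for (k in seq_len(n_timepoints)) {
    r <- unlist(jumps[[k]], use.names = FALSE)
    if (is.null(r)) r <- numeric(0)
    n_over <- n_over + sum(r > max_jump)
    jumps[[k]] <- r[r <= max_jump]
  }
  structure(
    list(
      jumps = jumps, dt = trajs$dt,
      settings = list(n_timepoints = as.integer(n_timepoints),
                      jumps_to_consider = as.integer(jumps_to_consider),
                      max_jump = max_jump, bin_width = bin_width,
                      min_len = as.integer(min_len)),
      n_tracks = length(keep$tracks), n_over_max = n_over,
      age_counts = age_counts,
      condition_label = trajs$condition_label
    ),
    class = "spt_jumps"
  )
}

#' @export
print.spt_jumps <- function(x, ...) {
  cat(sprintf("Jump-length data: %d tracks, dt = %g s\n", x$n_tracks, x$dt))
  for (k in seq_along(x$jumps)) {
    cat(sprintf("  k=%d (%g ms): %d jumps\n", k, k * x$dt * 1000,
                length(x$jumps[[k]])))
  }
  invisible(x)
}

# Empirical CDF of each interval's jumps evaluated at the bin-edge grid.
.jump_ecdf <- function(jumps) {
  bw <- jumps$settings$bin_width
  edges <- seq(bw, jumps$settings$max_jump, by = bw)
  lapply(jumps$jumps, function(r) {
    if (length(r) == 0) return(NULL)
    stats::ecdf(r)(edges)
  })
}

# Effective axial survival weight for the free term at interval multiple k.
# With at most J jumps taken per trajectory per interval, compiled jumps
# start at track ages 0..J-1, so the free population contributing them has
# survived i extra frames; the survival averaged over those start ages is
# used, weighted by the observed age composition of the compiled jumps
# (which reflects photobleaching and track-length attrition). A jump also
# requires its track to pass the minimum-length filter, i.e. to survive at
# least min_len - 1 transitions. With J = 1 and min_len <= k + 1 this
# reduces to the plain z_correction at k*dt.
.zbar <- function(k, dt, dz, d_free, jumps_to_consider, age_correction,
                  min_len = 3L, age_weights = NULL) {
  if (!age_correction) return(z_correction(k * dt, dz, d_free))
  ages <- seq_len(jumps_to_consider) - 1L
  frames_needed <- pmax(ages + k, min_len - 1L)
  s <- z_correction(frames_needed * dt, dz, d_free)
  if (is.null(age_weights) || sum(age_weights) == 0) {
    return(mean(s))
  }
  sum(s * age_weights) / sum(age_weights)
}

#' Fit the two-state model to jump-length CDFs
#'
#' Bounded least squares jointly across interval multiples: the model CDF
#' (see [two_state_cdf()]), truncation-renormalized at `max_jump`, is
#' matched to each interval's empirical CDF on the bin-edge grid, and the
#' summed squared deviation is minimized with the Levenberg-Marquardt
#' algorithm under box bounds, restarted from `n_iterations` seeded random
#' initializations; the best objective wins.
#'
#' The free-term weight at interval `k` uses a jump-age-averaged axial
#' survival `mean(z_correction((i + k) dt))` over jump start ages
#' `i = 0..jumps_to_consider-1`, because compiled jumps do not all start at
#' track birth (set `age_correction = FALSE` for the bare
#' `z_correction(k dt)`).
#'
#' @param jumps an [compile_jumps()] result with jumps in at least 2
#'   intervals.
#' @param bounds parameter box bounds, as [two_state_bounds()].
#' @param n_iterations number of random starts (default 3).
#' @param seed integer seed for the starts.
#' @param sigma `NULL` to fit the localization error from the data
#'   (default), or a fixed value in um.
#' @param dz axial detection range, um (fixed per dye: 0.65 JF646 / 0.60
#'   JF552).
#' @param age_correction see Details.
#' @return An object of class `spt_twostate` with elements `params`
#'   ([two_state_params()]), `objective` (sum of squared CDF residuals),
#'   `converged`, `n_iterations_used`, `se` (residual-based standard
#'   errors), `curves` (per-interval empirical and model CDFs),
#'   `n_jumps` per interval, and the fit settings.
#' @export
fit_two_state <- function(jumps, bounds = two_state_bounds(),
                          n_iterations = 3, seed = NULL, sigma = NULL,
                          dz = 0.65, age_correction = TRUE) {
  stopifnot(inherits(jumps, "spt_jumps"))
  check_number(n_iterations, "n_iterations", lower = 1, integer = TRUE)
  check_number(dz, "dz", lower = 0, strict_lower = TRUE)
  ec <- .jump_ecdf(jumps)
  ks <- which(!vapply(ec, is.null, logical(1)))
  if (length(ks) < 2) {
    stop("need jumps in at least 2 intervals to fit", call. = FALSE)
  }
  bw <- jumps$settings$bin_width
  edges <- seq(bw, jumps$settings$max_jump, by = bw)
  rmax <- jumps$settings$max_jump
  dt <- jumps$dt
  J <- jumps$settings$jumps_to_consider
  fit_sigma <- is.null(sigma)
  par_names <- if (fit_sigma) c("f_bound", "d_bound", "d_free", "sigma") else
    c("f_bound", "d_bound", "d_free")
  lower <- bounds$lower[par_names]
  upper <- bounds$upper[par_names]

  model_cdfs <- function(theta) {
    f1 <- theta[["f_bound"]]; d1 <- theta[["d_bound"]]
    d2 <- theta[["d_free"]]
    sg <- if (fit_sigma) theta[["sigma"]] else sigma
    f2 <- 1 - f1
    lapply(ks, function(k) {
      z <- .zbar(k, dt, dz, d2, J, age_correction,
                 min_len = jumps$settings$min_len,
                 age_weights = jumps$age_counts[k, ])
      v1 <- d1 * k * dt + sg^2
      v2 <- d2 * k * dt + sg^2
      num <- f1 * .rayleigh_cdf(edges, v1) + z * f2 * .rayleigh_cdf(edges, v2)
      den <- f1 * .rayleigh_cdf(rmax, v1) + z * f2 * .rayleigh_cdf(rmax, v2)
      num / den
    })
  }
  residual_fn <- function(theta) {
    names(theta) <- par_names
    mc <- model_cdfs(theta)
    unlist(lapply(seq_along(ks), function(i) mc[[i]] - ec[[ks[i]]]),
           use.names = FALSE)
  }

  # Stratified (Latin-hypercube) random starts: each parameter's range is
  # split into n_iterations strata, one draw per stratum, strata permuted
  # independently per parameter; diffusion coefficients are drawn on a log
  # scale. This keeps the starts random and seeded while guaranteeing that
  # they spread across the box (a start with low d_free can stall in a
  # degenerate all-bound corner).
  starts <- with_seed(seed, {
    np <- length(par_names)
    u <- matrix(stats::runif(np * n_iterations), nrow = n_iterations)
    for (p in seq_len(np)) {
      strata <- sample.int(n_iterations)
      u[, p] <- (strata - 1 + u[, p]) / n_iterations
    }
    colnames(u) <- par_names
    lapply(seq_len(n_iterations), function(i) {
      th <- numeric(np)
      names(th) <- par_names
      for (p in par_names) {
        if (p %in% c("d_bound", "d_free")) {
          th[p] <- exp(log(lower[p]) + u[i, p] * (log(upper[p]) - log(lower[p])))
        } else {
          th[p] <- lower[p] + u[i, p] * (upper[p] - lower[p])
        }
      }
      th
    })
  })
  best <- NULL
  best_obj <- Inf
  any_converged <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = residual_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    obj <- fit$deviance
    conv <- fit$info %in% 1:4
    any_converged <- any_converged || conv
    if (obj < best_obj) {
      best <- fit
      best_obj <- obj
    }
  }
  if (is.null(best)) {
    stop("two-state fit failed from every start", call. = FALSE)
  }
  if (!any_converged) {
    warning("two-state fit: no start converged; returning best effort",
            call. = FALSE)
  }
  theta <- best$par
  names(theta) <- par_names
  sg <- if (fit_sigma) theta[["sigma"]] else sigma
  params <- two_state_params(theta[["f_bound"]], theta[["d_bound"]],
                             theta[["d_free"]], sg, dz = dz, bounds = bounds)
  se <- rep(NA_real_, length(par_names))
  names(se) <- par_names
  se_try <- tryCatch({
    dof <- length(best$fvec) - length(par_names)
    cov <- solve(best$hessian) * best$deviance / dof
    sqrt(pmax(diag(cov), 0))
  }, error = function(e) NULL)
  if (!is.null(se_try)) se <- stats::setNames(se_try, par_names)

  mc <- model_cdfs(theta)
  curves <- lapply(seq_along(ks), function(i) {
    data.frame(r = edges, ecdf = ec[[ks[i]]], model = mc[[i]],
               residual = mc[[i]] - ec[[ks[i]]])
  })
  names(curves) <- paste0("k", ks)

  structure(
    list(params = params, objective = best_obj,
         converged = any_converged && best$info %in% 1:4,
         n_iterations_used = as.integer(n_iterations), se = se,
         sigma_fitted = fit_sigma, curves = curves,
         n_jumps = vapply(jumps$jumps, length, integer(1)),
         intervals_used = ks, dt = dt, dz = dz,
         age_correction = age_correction, age_counts = jumps$age_counts,
         settings = jumps$settings,
         seed = seed, condition_label = jumps$condition_label),
    class = "spt_twostate"
  )
}
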