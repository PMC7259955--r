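#' @export
print.spt_twostate <- function(x, ...) {
  p <- x$params
  cat("Two-state jump-length fit\n")
  if (!is.null(x$condition_label) && !is.na(x$condition_label)) {
    cat(sprintf("  condition: %s\n", x$condition_label))
  }
  cat(sprintf("  F_bound: %.3f (%.1f%%)%s\n", p$f_bound, 100 * p$f_bound,
              if (is.finite(x$se["f_bound"]))
                sprintf("  [SE %.3f]", x$se["f_bound"]) else ""))
  cat(sprintf("  D_bound: %.4f um^2/s   D_free: %.3f um^2/s\n",
              p$d_bound, p$d_free))
  cat(sprintf("  sigma: %.4f um (%s)   dz: %.2f um\n", p$sigma,
              if (x$sigma_fitted) "fitted" else "fixed", x$dz))
  cat(sprintf("  objective (sum sq CDF residual): %.5g over %d intervals\n",
              x$objective, length(x$intervals_used)))
  cat(sprintf("  jumps per interval: %s\n",
              paste(x$n_jumps, collapse = ", ")))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' @export
coef.spt_twostate <- function(object, ...) {
  p <- object$params
  c(f_bound = p$f_bound, d_bound = p$d_bound, d_free = p$d_free,
    sigma = p$sigma)
}

#' @export
summary.spt_twostate <- function(object, ...) {
  est <- coef(object)
  se <- object$se[names(est)]
  out <- data.frame(estimate = est, se = as.numeric(se))
  rownames(out) <- names(est)
  structure(list(coefficients = out, objective = object$objective,
                 converged = object$converged,
                 n_jumps = object$n_jumps,
                 condition_label = object$condition_label),
            class = "summary.spt_twostate")
}

#' @export
print.summary.spt_twostate <- function(x, ...) {
  cat("Two-state jump-length fit\n")
  print(x$coefficients)
  cat(sprintf("objective: %.5g, converged: %s, total jumps: %d\n",
              x$objective, x$converged, sum(x$n_jumps)))
  invisible(x)
}

#' Model CDF of a fitted two-state model
#'
#' @param object an `spt_twostate` fit.
#' @param r displacements (um) at which to evaluate; defaults to the fit's
#'   bin-edge grid.
#' @param interval interval multiple k (default 1).
#' @param ... unused.
#' @return Model CDF values (truncation-renormalized at the fit's max jump),
#'   using the fitted effective axial weight.
#' @export
predict.spt_twostate <- function(object, r = NULL,
                                 interval = 1, ...) {
  if (is.null(r)) {
    r <- object$curves[[1]]$r
  }
  p <- object$params
  k <- as.integer(interval)
  z <- .zbar(k, object$dt, object$dz, p$d_free,
             object$settings$jumps_to_consider, object$age_correction,
             min_len = object$settings$min_len,
             age_weights = if (!is.null(object$age_counts))
               object$age_counts[k, ] else NULL)
  v1 <- p$d_bound * k * object$dt + p$sigma^2
  v2 <- p$d_free * k * object$dt + p$sigma^2
  f1 <- p$f_bound
  f2 <- 1 - f1
  rmax <- object$settings$max_jump
  num <- f1 * .rayleigh_cdf(r, v1) + z * f2 * .rayleigh_cdf(r, v2)
  den <- f1 * .rayleigh_cdf(rmax, v1) + z * f2 * .rayleigh_cdf(rmax, v2)
  num / den
}

#' @export
residuals.spt_twostate <- function(object, ...) {
  unlist(lapply(object$curves, function(cv) cv$residual), use.names = FALSE)
}

#' Diagnostic plot of empirical vs model jump-length CDFs
#'
#' One panel per frame interval: empirical CDF (points) against the fitted
#' two-state model CDF (line).
#'
#' @param x an `spt_twostate` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spt_twostate <- function(x, ...) {
  ks <- x$intervals_used
  nk <- length(ks)
  oldpar <- graphics::par(mfrow = grDevices::n2mfrow(nk),
                          mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  for (i in seq_len(nk)) {
    cv <- x$curves[[i]]
    graphics::plot(cv$r, cv$ecdf, pch = ".", cex = 2, xlab = "r (um)",
                   ylab = "CDF",
                   main = sprintf("%g ms", ks[i] * x$dt * 1000), ...)
    graphics::lines(cv$r, cv$model, col = "red3", lwd = 1.5)
  }
  invisible(x)
}

#' Simulate trajectories from a fitted two-state model
#'
#' Closes the loop: draws synthetic trajectories from a [sim_config()] whose
#' generative parameters equal the fitted ones.
#'
#' @param object an `spt_twostate` fit.
#' @param nsim number of molecules (default 1000).
#' @param seed integer seed.
#' @param ... further [sim_config()] overrides.
#' @return A [trajectory_set()].
#' @export
simulate.spt_twostate <- function(object, nsim = 1000, seed = NULL, ...) {
  p <- object$params
  cfg <- sim_config(n_molecules = nsim, f_bound = p$f_bound,
                    d_bound = p$d_bound, d_free = p$d_free,
                    sigma_loc = p$sigma, dt = object$dt, dz = object$dz,
                    seed = seed, ...)
  simulate_trajectories(cfg)
}
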