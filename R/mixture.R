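#' Two-component Gaussian mixture fit of log10 D values
#'
#' Maximum-likelihood EM fit of a two-component univariate Gaussian mixture
#' to per-trajectory `log10(D)` values. The component with the smaller mean
#' is labeled "slow" (chromatin-bound); its weight is the mixture estimate
#' of the chromatin-bound fraction. Fitting operates on the raw values, not
#' on binned histogram counts.
#'
#' The EM is restarted from 10 deterministic initializations (five
#' quantile-split partitions and five quantile-pair placements); the fit
#' with the best log-likelihood wins, ties broken by the first. Convergence:
#' relative log-likelihood change below `1e-8` (up to 1000 iterations);
#' component SDs are floored at `1e-3` log10 units to keep the likelihood
#' bounded.
#'
#' @param log10_ds numeric vector of log10 diffusion coefficients (>= 50
#'   values).
#' @param n_components number of components; only 2 is supported.
#' @return An object of class `spt_mixture`: `weights`, `means`, `sds`
#'   (each length 2, slow then fast), `loglik`, `converged`, `n`, `n_iter`.
#' @export
fit_mixture <- function(log10_ds, n_components = 2) {
  x <- as.numeric(log10_ds)
  if (!identical(as.integer(n_components), 2L)) {
    stop("only n_components = 2 is supported", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) stop("log10_ds must be finite", call. = FALSE)
  if (length(x) < 50) {
    stop(sprintf("need at least 50 values to fit a mixture (got %d)",
                 length(x)), call. = FALSE)
  }
  if (diff(range(x)) < 1e-6) stop("degenerate distribution", call. = FALSE)

  best <- NULL
  for (init in .mixture_inits(x)) {
    fit <- .em_two_gauss(x, init)
    if (is.null(best) || (fit$loglik > best$loglik + 1e-12)) best <- fit
  }
  ord <- order(best$means)
  structure(
    list(weights = best$weights[ord], means = best$means[ord],
         sds = best$sds[ord], loglik = best$loglik,
         converged = best$converged, n = length(x), n_iter = best$n_iter,
         se_weights = c(NA_real_, NA_real_), se_means = c(NA_real_, NA_real_),
         se_sds = c(NA_real_, NA_real_), n_boot = 0L),
    class = "spt_mixture"
  )
}

# Deterministic EM initializations: quantile splits and quantile pairs.
.mixture_inits <- function(x) {
  inits <- list()
  for (p in c(0.3, 0.4, 0.5, 0.6, 0.7)) {
    s <- stats::quantile(x, p, names = FALSE)
    lo <- x[x <= s]; hi <- x[x > s]
    if (length(lo) < 2 || length(hi) < 2) next
    inits[[length(inits) + 1L]] <- list(
      weights = c(length(lo), length(hi)) / length(x),
      means = c(mean(lo), mean(hi)),
      sds = pmax(c(stats::sd(lo), stats::sd(hi)), 1e-3)
    )
  }
  sdx <- stats::sd(x)
  for (q in list(c(0.10, 0.90), c(0.20, 0.80), c(0.25, 0.75),
                 c(0.15, 0.85), c(0.35, 0.65))) {
    mu <- stats::quantile(x, q, names = FALSE)
    if (diff(mu) < 1e-8) next
    inits[[length(inits) + 1L]] <- list(
      weights = c(0.5, 0.5), means = mu, sds = rep(max(sdx / 2, 1e-3), 2)
    )
  }
  inits
}

.em_two_gauss <- function(x, init, max_iter = 1000, tol = 1e-8,
                          sd_floor = 1e-3) {
  n <- length(x)
  w <- init$weights; mu <- init$means; s <- pmax(init$sds, sd_floor)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], s[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break # one component vanished
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    s <- c(sqrt(sum(g1 * (x - mu[1])^2) / n1),
           sqrt(sum((1 - g1) * (x - mu[2])^2) / n2))
    s <- pmax(s, sd_floor)
    w <- c(n1, n2) / n
  }
  list(weights = w, means = mu, sds = s, loglik = ll_old,
       converged = converged, n_iter = iter)
}

#' @export
print.spt_mixture <- function(x, ...) {
  cat("Two-component Gaussian mixture of log10 D\n")
  lab <- c("slow (bound)", "fast (free)")
  for (i in 1:2) {
    cat(sprintf("  %-13s weight %.3f%s  mean %.3f  sd %.3f\n", lab[i],
                x$weights[i],
                if (x$n_boot > 0) sprintf(" (SE %.3f)", x$se_weights[i]) else "",
                x$means[i], x$sds[i]))
  }
  cat(sprintf("  n = %d, logLik = %.2f, converged: %s", x$n, x$loglik,
              x$converged))
  if (x$n_boot > 0) cat(sprintf(", bootstrap reps: %d", x$n_boot))
  cat("\n")
  invisible(x)
}

#' @export
coef.spt_mixture <- function(object, ...) {
  c(f_slow = object$weights[1], mean_slow = object$means[1],
    sd_slow = object$sds[1], f_fast = object$weights[2],
    mean_fast = object$means[2], sd_fast = object$sds[2])
}

#' @export
summary.spt_mixture <- function(object, ...) {
  est <- coef(object)
  se <- c(object$se_weights[1], object$se_means[1], object$se_sds[1],
          object$se_weights[2], object$se_means[2], object$se_sds[2])
  out <- data.frame(estimate = est, boot_se = se)
  rownames(out) <- names(est)
  out
}

#' Bootstrap standard errors for the mixture parameters
#'
#' Resamples the per-trajectory `log10(D)` values with replacement (the
#' trajectory is the resampling unit), refits the two-component mixture on
#' each replicate, orders components by mean to resolve label switching, and
#' reports the standard deviation of each parameter across replicates as its
#' standard error.
#'
#' @param log10_ds numeric vector of log10 diffusion coefficients.
#' @param n_boot number of bootstrap replicates (default 100).
#' @param seed integer seed for the resampling.
#' @return An `spt_mixture` (the full-data fit) with `se_weights`,
#'   `se_means`, `se_sds` and `n_boot` filled in, plus the replicate
#'   parameter matrix in `attr(, "replicates")`.
#' @export
bootstrap_mixture <- function(log10_ds, n_boot = 100, seed = NULL) {
  check_number(n_boot, "n_boot", lower = 2, integer = TRUE)
  if (n_boot < 100) {
    warning("fewer than 100 bootstrap replicates; SEs will be noisy",
            call. = FALSE)
  }
  x <- as.numeric(log10_ds)
  fit <- fit_mixture(x)
  reps <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_boot, ncol = 6)
    colnames(out) <- c("f_slow", "mean_slow", "sd_slow",
                       "f_fast", "mean_fast", "sd_fast")
    for (b in seq_len(n_boot)) {
      xb <- x[sample.int(length(x), replace = TRUE)]
      fb <- tryCatch(fit_mixture(xb), error = function(e) NULL)
      if (!is.null(fb)) {
        out[b, ] <- c(fb$weights[1], fb$means[1], fb$sds[1],
                      fb$weights[2], fb$means[2], fb$sds[2])
      }
    }
    out
  })
  ses <- apply(reps, 2, stats::sd, na.rm = TRUE)
  fit$se_weights <- c(ses["f_slow"], ses["f_fast"])
  fit$se_means <- c(ses["mean_slow"], ses["mean_fast"])
  fit$se_sds <- c(ses["sd_slow"], ses["sd_fast"])
  fit$n_boot <- as.integer(n_boot)
  attr(fit, "replicates") <- reps
  fit
}
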