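test_that("jump compilation counts follow the cap and max-jump rules", {
  # one 3-frame track: 2 jumps at k=1, 1 at k=2, 0 beyond
  tr <- trajectory_set(list(a = make_track(c(0, 0.1, 0.2))), dt = 0.01)
  j <- compile_jumps(tr, n_timepoints = 3)
  expect_equal(vapply(j$jumps, length, integer(1)), c(2L, 1L, 0L))

  # a 20-frame track contributes exactly jumps_to_consider = 4 per interval
  tr2 <- trajectory_set(list(a = make_track(cumsum(rep(0.05, 20)))), dt = 0.01)
  j2 <- compile_jumps(tr2, n_timepoints = 6, jumps_to_consider = 4)
  expect_equal(vapply(j2$jumps, length, integer(1)), rep(4L, 6))

  # displacements beyond 1.2 um are excluded
  tr3 <- trajectory_set(list(a = make_track(c(0, 1.3, 2.6))), dt = 0.01)
  j3 <- compile_jumps(tr3, n_timepoints = 2)
  expect_equal(length(j3$jumps[[1]]), 0L)
  expect_equal(j3$n_over_max, 3L)

  # earliest-first: the first 4 jumps of the track are the ones taken
  x <- c(0.01 * (1:5), 0.5 + 0.01 * (1:10))
  tr4 <- trajectory_set(list(a = make_track(cumsum(x))), dt = 0.01)
  j4 <- compile_jumps(tr4, n_timepoints = 1, jumps_to_consider = 4)
  expect_equal(j4$jumps[[1]], x[2:5])

  expect_error(compile_jumps(trajectory_set(list(), dt = 0.01)), "no trajectories")
})

test_that("single-state displacement law identities hold", {
  d <- 0.7; tau <- 0.02
  expect_equal(single_state_pdf(0, d, tau), 0)
  expect_equal(single_state_cdf(sqrt(4 * d * tau), d, tau), 1 - exp(-1))
  q <- integrate(single_state_pdf, 0, Inf, d = d, delta_tau = tau,
                 rel.tol = 1e-10)
  expect_lt(abs(q$value - 1), 1e-6)
  # CDF is the integral of the density
  r0 <- 0.13
  q2 <- integrate(single_state_pdf, 0, r0, d = d, delta_tau = tau,
                  rel.tol = 1e-10)
  expect_equal(q2$value, single_state_cdf(r0, d, tau), tolerance = 1e-9)
  expect_error(single_state_pdf(0.1, 0, tau), "d")
  expect_error(single_state_cdf(0.1, d, 0), "delta_tau")
})

test_that("z correction limits, monotonicity and Monte-Carlo agreement", {
  expect_equal(z_correction(0.05, 0.65, 0), 1)
  expect_gt(z_correction(0.01, 1000, 1.0), 0.999)
  # monotone: decreasing in d and delta_tau, increasing in dz
  taus <- seq(0.01, 0.06, by = 0.01)
  expect_true(all(diff(z_correction(taus, 0.6, 1.0)) < 0))
  ds <- c(0.15, 0.5, 1, 2, 5)
  expect_true(all(diff(vapply(ds, function(d) z_correction(0.03, 0.6, d),
                              numeric(1))) < 0))
  expect_lt(z_correction(0.03, 0.6, 1), z_correction(0.03, 0.65, 1))
  # survival from a uniform start at t = 0 is 1
  expect_equal(z_correction(0, 0.65, 2), 1)
  # spot check against the Monte-Carlo absorbing-slab oracle
  set.seed(71)
  mc <- mc_slab_survival(0.03, 0.6, 1.18, n_walkers = 1e5)
  expect_lt(abs(z_correction(0.03, 0.6, 1.18) - mc), 0.005)
})

test_that("two-state law reduces correctly in degenerate corners", {
  tau <- 0.01
  # F1 = 1: single-state law with effective variance D1 tau + sigma^2
  p1 <- two_state_params(1, 0.03, 1.0, 0.03, dz = 0.65)
  r <- seq(0, 0.8, by = 0.01)
  veff <- 0.03 * tau + 0.03^2
  expect_equal(two_state_pdf(r, tau, p1),
               r / (2 * veff) * exp(-r^2 / (4 * veff)))
  # sigma -> 0 (at the bound edge 0.01 use exact algebra instead): with
  # zcorr forced to 1, F1 = 0.5, D1 = D2 the law collapses to single-state
  relaxed <- list(
    lower = c(f_bound = 0, d_bound = 0.001, d_free = 0.001, sigma = 0.01),
    upper = c(f_bound = 1, d_bound = 0.1, d_free = 5, sigma = 0.1)
  )
  pc <- two_state_params(0.5, 0.05, 0.05, 0.01, dz = 0.65, bounds = relaxed)
  veq <- 0.05 * tau + 0.01^2
  expect_equal(two_state_pdf(r, tau, pc, zcorr = 1),
               r / (2 * veq) * exp(-r^2 / (4 * veq)))
  expect_equal(two_state_cdf(r, tau, pc, zcorr = 1),
               1 - exp(-r^2 / (4 * veq)))
  # unnormalized mass below r -> F1 + Z F2; normalized -> 1
  p2 <- two_state_params(0.4, 0.03, 1.5, 0.03, dz = 0.6)
  z <- z_correction(tau, 0.6, 1.5)
  expect_equal(two_state_cdf(10, tau, p2), 0.4 + z * 0.6, tolerance = 1e-12)
  expect_equal(two_state_cdf(10, tau, p2, normalize = TRUE), 1,
               tolerance = 1e-12)
  # out-of-bounds parameters are rejected
  expect_error(two_state_params(0.5, 0.5, 1, 0.03), "d_bound")
  expect_error(two_state_params(1.2, 0.03, 1, 0.03), "f_bound")
})

test_that("model CDF matches simulated data at the generative parameters", {
  # first-jump-only compilation makes the bare z correction exact
  cfg <- sim_config(n_molecules = 60000, f_bound = 0.5, d_bound = 0.01,
                    d_free = 1.0, sigma_loc = 0.03, dt = 0.01, dz = 0.6,
                    bleach_prob = 0.1, min_track_len = 2, seed = 55)
  tr <- simulate_trajectories(cfg)
  j <- compile_jumps(tr, n_timepoints = 3, jumps_to_consider = 1,
                     min_len = 2)
  expect_gt(sum(lengths(j$jumps)), 1e5)
  p <- two_state_params(0.5, 0.01, 1.0, 0.03, dz = 0.6)
  for (k in 1:3) {
    r <- j$jumps[[k]]
    expect_gt(length(r), 2e4)
    grid <- seq(0.01, 1.2, by = 0.01)
    emp <- stats::ecdf(r)(grid)
    mod <- two_state_cdf(grid, k * 0.01, p, normalize = TRUE)
    mod <- mod / two_state_cdf(1.2, k * 0.01, p, normalize = TRUE)
    expect_lt(max(abs(emp - mod)), 0.02)
  }
})

test_that("two-state fit recovers generative parameters from jump data", {
  cfg <- sim_config(n_molecules = 6000, f_bound = 0.5, d_bound = 0.01,
                    d_free = 1.0, sigma_loc = 0.03, dt = 0.01, dz = 0.6,
                    bleach_prob = 0.1, seed = 60)
  tr <- simulate_trajectories(cfg)
  j <- compile_jumps(tr)
  expect_gte(sum(vapply(j$jumps, length, integer(1))), 3e4)
  fit <- fit_two_state(j, seed = 61, dz = 0.6)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$f_bound - 0.5), 0.03)
  expect_lt(abs(fit$params$d_free - 1.0) / 1.0, 0.10)
  # determinism: same data, same seed, identical fit
  fit2 <- fit_two_state(j, seed = 61, dz = 0.6)
  expect_identical(coef(fit), coef(fit2))
})

test_that("an all-bound simulation fits to a bound fraction near 1", {
  cfg <- sim_config(n_molecules = 3000, f_bound = 1, d_bound = 0.03,
                    d_free = 1.0, sigma_loc = 0.03, dt = 0.01, seed = 62)
  tr <- simulate_trajectories(cfg)
  fit <- fit_two_state(compile_jumps(tr), seed = 63, dz = 0.65)
  expect_gte(fit$params$f_bound, 0.97)
})

test_that("fit object methods are coherent", {
  cfg <- sim_config(n_molecules = 1500, f_bound = 0.6, d_bound = 0.02,
                    d_free = 1.2, sigma_loc = 0.03, seed = 64)
  tr <- simulate_trajectories(cfg)
  fit <- fit_two_state(compile_jumps(tr), seed = 65, dz = 0.65)
  expect_named(coef(fit), c("f_bound", "d_bound", "d_free", "sigma"))
  s <- summary(fit)
  expect_s3_class(s, "summary.spt_twostate")
  expect_equal(s$coefficients["f_bound", "estimate"],
               unname(coef(fit)["f_bound"]))
  # empirical CDFs are monotone from ~0 to 1; model CDF monotone too
  for (cv in fit$curves) {
    expect_true(all(diff(cv$ecdf) >= 0))
    expect_equal(cv$ecdf[length(cv$ecdf)], 1)
    expect_true(all(diff(cv$model) >= 0))
  }
  pr <- predict(fit, r = c(0.05, 0.2, 1.2), interval = 2)
  expect_true(all(diff(pr) > 0))
  expect_equal(pr[3], 1, tolerance = 1e-12)
  expect_equal(length(residuals(fit)),
               sum(vapply(fit$curves, nrow, integer(1))))
  # simulate() round-trips the fitted parameters into a config
  tr2 <- simulate(fit, nsim = 100, seed = 1)
  expect_s3_class(tr2, "trajectory_set")
  expect_equal(tr2$provenance$config$f_bound, fit$params$f_bound)
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
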