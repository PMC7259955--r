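test_that("config validation names the offending field", {
  expect_error(sim_config(f_bound = 1.2), "f_bound")
  expect_error(sim_config(d_free = -1), "d_free")
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(dz = -0.1), "dz")
  expect_error(sim_config(bleach_prob = 1), "bleach_prob")
  expect_error(sim_config(min_track_len = 1), "min_track_len")
  expect_error(sim_config(sigma_loc = -0.01), "sigma_loc")
})

test_that("zero diffusion and zero noise give exactly zero displacements", {
  cfg <- sim_config(n_molecules = 50, f_bound = 0.5, d_bound = 0, d_free = 0,
                    sigma_loc = 0, bleach_prob = 0.2, seed = 1)
  tr <- simulate_trajectories(cfg)
  expect_gt(length(tr$tracks), 0)
  for (m in tr$tracks) {
    expect_identical(max(abs(diff(m[, "x"]))), 0)
    expect_identical(max(abs(diff(m[, "y"]))), 0)
  }
})

test_that("all-bound simulations never terminate by axial exit", {
  cfg <- sim_config(n_molecules = 300, f_bound = 1, d_bound = 0.03,
                    d_free = 1.2, bleach_prob = 0.1, seed = 2)
  tr <- simulate_trajectories(cfg)
  expect_true(all(tr$provenance$state == "bound"))
  expect_false(any(tr$provenance$end_reason == "z_exit"))
})

test_that("mean squared one-frame displacement matches 4 D dt", {
  d <- 1.0; dt <- 0.01
  cfg <- sim_config(n_molecules = 3000, f_bound = 0, d_free = d,
                    sigma_loc = 0, dt = dt, dz = 1e6, bleach_prob = 0.1,
                    seed = 42)
  tr <- simulate_trajectories(cfg)
  r2 <- unlist(lapply(tr$tracks, function(m) diff(m[, "x"])^2 + diff(m[, "y"])^2))
  expect_gte(length(r2), 1e4)
  # E[r^2] = 4 D dt; r^2/(2 D dt) is chi-squared(2), SD of mean = 4 D dt / sqrt(n)
  se <- 4 * d * dt / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 4 * d * dt), 3 * se)
})

test_that("per-axis displacement variance converges to 2 D dt", {
  d <- 0.5; dt <- 0.01
  cfg <- sim_config(n_molecules = 3000, f_bound = 0, d_free = d,
                    sigma_loc = 0, dt = dt, dz = 1e6, bleach_prob = 0.1,
                    seed = 5)
  tr <- simulate_trajectories(cfg)
  dx <- unlist(lapply(tr$tracks, function(m) diff(m[, "x"])))
  expect_gte(length(dx), 1e4)
  v <- 2 * d * dt
  se <- v * sqrt(2 / length(dx)) # var of sample variance of normals
  expect_lt(abs(stats::var(dx) - v), 3 * se)
})

test_that("noisy displacement lengths follow the effective-variance law", {
  d <- 0.8; dt <- 0.01; sigma <- 0.04
  cfg <- sim_config(n_molecules = 2000, f_bound = 0, d_free = d,
                    sigma_loc = sigma, dt = dt, dz = 1e6, bleach_prob = 0.15,
                    seed = 8)
  tr <- simulate_trajectories(cfg)
  r <- unlist(lapply(tr$tracks, function(m) {
    sqrt(diff(m[, "x"])^2 + diff(m[, "y"])^2)
  }))
  # successive observed displacements share localization noise, so thin to
  # every second jump for an (approximately) independent KS sample
  r <- r[seq(1, length(r), by = 2)]
  veff <- d * dt + sigma^2
  ks <- max(abs(stats::ecdf(r)(sort(r)) - (1 - exp(-sort(r)^2 / (4 * veff)))))
  expect_lt(ks, 1.628 / sqrt(length(r))) # alpha = 0.01 critical value
})

test_that("track lengths without axial exit are geometric", {
  q <- 0.25
  cfg <- sim_config(n_molecules = 4000, f_bound = 1, d_bound = 0.03,
                    bleach_prob = q, min_track_len = 2, seed = 13)
  tr <- simulate_trajectories(cfg)
  len <- track_lengths(tr)
  # conditional on length >= 2, L - 2 is geometric(q)
  obs <- table(factor(pmin(len - 2L, 8L), levels = 0:8))
  p <- stats::dgeom(0:7, q)
  p <- c(p, 1 - sum(p))
  chi <- stats::chisq.test(as.vector(obs), p = p)
  expect_gt(chi$p.value, 0.01)
})

test_that("same seed gives identical output", {
  cfg <- condition_preset("h2az_wt", n_molecules = 200, seed = 77)
  expect_identical(simulate_trajectories(cfg), simulate_trajectories(cfg))
})

test_that("localization table matches trajectory content", {
  cfg <- sim_config(n_molecules = 1, f_bound = 1, bleach_prob = 0,
                    n_frames = 10, stagger_starts = FALSE, seed = 3)
  locs <- simulate_localizations(cfg)
  expect_equal(nrow(locs), 10)
  expect_equal(locs$frame, 1:10)

  cfg2 <- condition_preset("h2b_wt", n_molecules = 50, seed = 4)
  locs2 <- simulate_localizations(cfg2)
  tr2 <- attr(locs2, "truth_tracks")
  expect_equal(nrow(locs2), sum(track_lengths(tr2)))
  expect_false(is.unsorted(locs2$frame))
  expect_equal(length(attr(locs2, "truth_id")), nrow(locs2))
})

test_that("condition presets carry the reported generative values", {
  p <- condition_preset("h2az_wt")
  expect_equal(p$f_bound, 0.82)
  expect_equal(p$d_free, 1.18)
  expect_equal(p$d_bound, 0.03)
  expect_equal(p$dz, 0.65)
  expect_equal(condition_preset("h2b_wt")$f_bound, 0.76)
  expect_equal(condition_preset("h2b_wt")$d_free, 1.29)
  expect_equal(condition_preset("swr1_wt")$f_bound, 0.47)
  expect_equal(condition_preset("swr1_swc2del")$f_bound, 0.21)
  expect_equal(condition_preset("swc5_norap")$f_bound, 0.79)
  expect_equal(condition_preset("swc5_aa")$f_bound, 0.49)
  expect_equal(condition_preset("swc5_rpb1_aa")$f_bound, 0.66)
  expect_equal(condition_preset("swc5_kin28_aa")$f_bound, 0.65)
  expect_equal(condition_preset("swc5_aa")$dz, 0.60)
  expect_error(condition_preset(""), "valid names")
  expect_error(condition_preset("nope"), "h2az_wt")
})

test_that("trajectory and config round-trip through text files", {
  cfg <- condition_preset("swr1_wt", n_molecules = 30, seed = 9)
  tr <- simulate_trajectories(cfg)
  f <- tempfile(fileext = ".csv")
  write_trajectories(tr, f)
  rt <- read_trajectories(f, dt = tr$dt)
  expect_equal(length(rt$tracks), length(tr$tracks))
  m0 <- tr$tracks[[1]]
  m1 <- rt$tracks[[names(tr$tracks)[1]]]
  expect_equal(unname(m1[, "x"]), unname(signif(m0[, "x"], 8)))

  locs <- simulate_localizations(cfg)
  fl <- tempfile(fileext = ".csv")
  write_localizations(locs, fl)
  rl <- read_localizations(fl)
  expect_equal(nrow(rl), nrow(locs))

  fc <- tempfile(fileext = ".json")
  write_sim_config(cfg, fc)
  cfg2 <- read_sim_config(fc)
  expect_equal(cfg2$f_bound, cfg$f_bound)
  expect_equal(cfg2$dz, cfg$dz)
  cfg3 <- read_sim_config(fc, f_bound = 0.1)
  expect_equal(cfg3$f_bound, 0.1)
})
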