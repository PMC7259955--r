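test_that("a single drifting molecule yields one full-length track", {
  # 1 px/frame drift, well under the 5 px gate
  px <- 0.107
  locs <- make_locs(frame = 1:8, x = px * (1:8), y = rep(0.5, 8))
  suppressMessages(tr <- link_localizations(locs, link_config(), dt = 0.01))
  expect_equal(length(tr$tracks), 1L)
  expect_equal(nrow(tr$tracks[[1]]), 8L)
  expect_equal(unname(tr$tracks[[1]][, "x"]), px * (1:8))
})

test_that("well-separated molecules are recovered exactly", {
  px <- 0.107
  f <- rep(1:6, each = 2)
  x <- c(rbind(0.1 + 0.02 * (1:6), 3.0 - 0.02 * (1:6)))
  truth <- rep(c("a", "b"), times = 6)
  locs <- make_locs(f, x, rep(1, 12), truth = truth)
  suppressMessages(tr <- link_localizations(locs, link_config(min_track_len = 2),
                                            dt = 0.01))
  expect_equal(length(tr$tracks), 2L)
  acc <- link_accuracy(locs, tr)
  expect_equal(acc$accuracy, 1)
  expect_equal(acc$n_true, 10L)
})

test_that("crossing molecules match the exhaustive minimum-cost assignment", {
  # two molecules approach within the gate on one frame transition;
  # compare every frame-pair assignment against the brute-force oracle
  set.seed(91)
  radius <- 5 * 0.107
  for (rep in 1:25) {
    m <- sample(1:4, 1)
    n <- sample(1:4, 1)
    fx <- runif(m, 0, 0.6); fy <- runif(m, 0, 0.6)
    tx <- runif(n, 0, 0.6); ty <- runif(n, 0, 0.6)
    got <- sptkin:::.assign_frame(fx, fy, tx, ty, radius^2)
    want <- match_brute(fx, fy, tx, ty, radius^2)
    got_card <- sum(!is.na(got))
    got_cost <- sum(((fx - tx[got])^2 + (fy - ty[got])^2)[!is.na(got)])
    expect_equal(got_card, want$card)
    expect_equal(got_cost, want$cost, tolerance = 1e-12)
  }

  # the canonical crossing pair: two tracks swap-or-not decided by cost
  a1 <- c(0.00, 0.10, 0.20); a2 <- c(0.40, 0.28, 0.16) # cross near frame 2-3
  locs <- make_locs(rep(1:3, each = 2), c(rbind(a1, a2)), rep(0, 6),
                    truth = rep(c("a", "b"), 3))
  suppressMessages(tr <- link_localizations(locs, link_config(min_track_len = 2),
                                            dt = 0.01))
  # assignment on each transition must equal the 2x2 brute-force optimum
  for (f in 1:2) {
    from <- c(a1[f], a2[f]); to <- c(a1[f + 1], a2[f + 1])
    want <- match_brute(from, c(0, 0), to, c(0, 0), radius^2)
    got <- sptkin:::.assign_frame(from, c(0, 0), to, c(0, 0), radius^2)
    expect_equal(got, want$assign)
  }
})

test_that("no link exceeds the gate radius and detections are partitioned", {
  cfg <- sim_config(n_molecules = 150, f_bound = 0.5, d_bound = 0.03,
                    d_free = 1.0, sigma_loc = 0.02, n_frames = 300,
                    seed = 92)
  locs <- simulate_localizations(cfg)
  lc <- link_config(max_jump_px = 5, min_track_len = 2)
  suppressMessages(tr <- link_localizations(locs, lc, dt = cfg$dt))
  radius <- lc$max_jump_px * lc$pixel_size
  steps <- unlist(lapply(tr$tracks, function(m) {
    sqrt(diff(m[, "x"])^2 + diff(m[, "y"])^2)
  }))
  expect_true(all(steps <= radius + 1e-12))
  rows <- unlist(tr$provenance$rows)
  expect_equal(anyDuplicated(rows), 0L)
  expect_lte(length(rows), nrow(locs))
})

test_that("linking is near-perfect at low density", {
  # ~50 molecules spread over 2000 frames in a 2x2 um field: sparse regime
  cfg <- condition_preset("h2az_wt", n_molecules = 400, seed = 93)
  locs <- simulate_localizations(cfg)
  suppressMessages(tr <- link_localizations(locs, link_config(min_track_len = 2),
                                            dt = cfg$dt))
  acc <- link_accuracy(locs, tr)
  expect_gte(acc$accuracy, 0.99)
})

test_that("length filter and edge cases behave", {
  tracks <- list(
    a = make_track(seq(0, 0.01, length.out = 2)),
    b = make_track(seq(0, 0.02, length.out = 3)),
    c = make_track(seq(0, 0.05, length.out = 6)),
    d = make_track(seq(0, 0.09, length.out = 10))
  )
  tr <- trajectory_set(tracks, dt = 0.01)
  expect_equal(length(suppressMessages(filter_min_length(tr, 6))$tracks), 2L)
  expect_equal(length(suppressMessages(filter_min_length(tr, 3))$tracks), 3L)
  empty <- trajectory_set(structure(list(), names = character(0)), dt = 0.01)
  expect_equal(length(suppressMessages(filter_min_length(empty, 3))$tracks), 0L)

  suppressMessages(e <- link_localizations(data.frame(frame = integer(),
                                                      x = numeric(),
                                                      y = numeric()),
                                           link_config(), dt = 0.01))
  expect_s3_class(e, "trajectory_set")
  expect_equal(length(e$tracks), 0L)
  bad <- data.frame(frame = c(-1L, 0L), x = c(0, 1), y = c(0, 1))
  expect_error(link_localizations(bad, link_config()), "negative")
})
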