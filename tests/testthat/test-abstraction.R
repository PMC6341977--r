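# Broken-stick abstraction and dive metrics.

test_that("V-dive reconstruction is exact with a degenerate bottom", {
  depth <- c(seq(0, 300, by = 1.5), seq(298.5, 0, by = -1.5))
  s <- abstract_dive(depth)
  expect_equal(s$dive$max_depth_m, 300)
  recon_err <- 0
  seg <- s$segments
  expect_equal(nrow(seg), 3L)
  # the apex is among the retained points; interior bottom is degenerate
  expect_true(300 %in% c(seg$depth_start_m, seg$depth_end_m))
  widths <- seg$t_end_s - seg$t_start_s
  expect_equal(min(widths), widths[2])
})

test_that("square dive yields three segments with a flat bottom", {
  depth <- c(seq(0, 200, by = 2), rep(200, 300), seq(198, 0, by = -2))
  s <- abstract_dive(depth)
  seg <- s$segments
  expect_equal(seg$role, c("descent", "bottom", "ascent"))
  expect_equal(seg$vertical_rate[2], 0)
  expect_lt(seg$vertical_rate[1], 0)  # sinking is negative (upward positive)
  expect_gt(seg$vertical_rate[3], 0)
})

test_that("non-dives are rejected and bad profiles error", {
  expect_message(expect_null(abstract_dive(c(0, 5, 10, 5, 0))), "non-dive")
  expect_message(expect_null(abstract_dive(rep(c(0, 12), 20))), "non-dive")
  expect_error(abstract_dive(seq(10, 300, length.out = 100)), "start and end")
})

test_that("abstraction recovers generating rates on noise-free trapezoids", {
  p <- generator_params("juvenile", seed = 8, drift_noise_sd = 0,
                        wiggle_amp_max = 1.0001, drift_dive_prob = 1)
  set.seed(3)
  for (r in 1:10) {
    dr <- runif(1, -0.25, 0.45)
    d <- simulate_dive(40, dr, p)
    s <- abstract_dive(d$depth, d$segments)
    true_rate <- (d$segments$depth_start_m - d$segments$depth_end_m) /
      (d$segments$t_end_s - d$segments$t_start_s)
    expect_lt(max(abs(s$segments$vertical_rate - true_rate)), 0.01)
    expect_equal(s$segments$vertical_rate[2], dr)
  }
})

test_that("segment durations and apportioned effort are conserved", {
  set.seed(11)
  p <- generator_params("juvenile", seed = 8)
  for (r in 1:10) {
    d <- simulate_dive(runif(1, 0, 200), runif(1, -0.25, 0.45), p)
    s <- abstract_dive(d$depth, d$segments)
    seg <- s$segments
    expect_identical(as.numeric(sum(seg$t_end_s - seg$t_start_s)),
                     as.numeric(s$dive$duration_s))
    expect_equal(sum(seg$effort_sum), sum(d$segments$effort_sum))
    expect_equal(sum(seg$prca_fraction * (seg$t_end_s - seg$t_start_s)),
                 sum(d$segments$prca_s))
    # max depth equals the raw profile maximum exactly
    expect_identical(s$dive$max_depth_m, max(d$depth))
  }
})

test_that("greedy selection matches the exhaustive minimax oracle", {
  set.seed(21)
  for (r in 1:25) {
    pr <- random_trapezoid_profile(200L)
    expect_identical(as.integer(broken_stick_points(pr$depth, 4L)),
                     as.integer(oracle_broken_stick(pr$depth)))
    # and the greedy points are exactly the generating corners
    expect_identical(as.integer(broken_stick_points(pr$depth, 4L)),
                     as.integer(c(1L, pr$corners, 200L)))
  }
})

test_that("extra broken-stick points collapse to the three roles", {
  depth <- c(seq(0, 200, by = 2), rep(c(200, 203, 199, 204), 75),
             seq(198, 0, by = -2))
  s <- abstract_dive(depth, n_points = 6L)
  expect_equal(nrow(s$segments), 5L)
  expect_equal(s$segments$role[1], "descent")
  expect_equal(s$segments$role[nrow(s$segments)], "ascent")
  expect_true(all(c("descent", "bottom", "ascent") %in% s$segments$role))
})

test_that("dive metrics convert units and match the raw-profile oracle", {
  # drift dive: abstracted corners coincide with the true segment corners,
  # so the raw-profile oracle applies exactly
  p <- generator_params("juvenile", seed = 8)
  set.seed(5)
  d <- simulate_dive(60, -0.15, p, force_drift = TRUE)
  s <- abstract_dive(d$depth, d$segments, surface_s = d$surface_s)
  m <- dive_metrics(s)
  o <- oracle_dive_metrics(d$depth, d$segments, d$surface_s)
  expect_equal(m$max_depth_m, o$max_depth_m)
  expect_equal(m$duration_min, o$duration_min)
  expect_equal(m$surface_min, o$surface_min)
  expect_equal(m$total_effort, o$total_effort, tolerance = 1e-6)
  expect_equal(m$bottom_prca_rate, o$bottom_prca_rate, tolerance = 1e-6)
  # 774 s is 12.9 min
  s$dive$duration_s <- 774
  expect_equal(dive_metrics(s)$duration_min, 12.9)
})

test_that("PrCA seconds map onto the bottom segment of a square dive", {
  depth <- c(seq(0, 200, by = 2), rep(200, 299), seq(198, 0, by = -2))
  n <- length(depth)                       # t = 0 .. n-1
  accel <- data.frame(t_start_s = c(0, 100, 399),
                      t_end_s = c(100, 399, n - 1),
                      effort_sum = c(700, 300, 700),
                      prca_s = c(0, 45, 0))
  s <- abstract_dive(depth, accel, surface_s = 70)
  m <- dive_metrics(s)
  o <- oracle_dive_metrics(depth, accel, 70)
  expect_equal(m$total_effort, o$total_effort, tolerance = 1e-6)
  expect_equal(m$bottom_prca_rate, o$bottom_prca_rate, tolerance = 1e-6)
  expect_equal(m$bottom_prca_rate, 45 / 299)
})

test_that("vectorised metrics agree with the per-dive path", {
  p <- small_juvenile_params(seed = 23, n = 1, days = 5)
  rec <- simulate_individual(p, 1, level = "profile")
  ab <- abstract_record(rec)
  mt <- divekit:::.metrics_table(ab$dives, ab$segments)
  for (k in c(1, 10, 25)) {
    s <- list(dive = ab$dives[k, ],
              segments = ab$segments[ab$segments$dive_id ==
                                       ab$dives$dive_id[k], ])
    m <- dive_metrics(s)
    row <- mt[mt$dive_id == ab$dives$dive_id[k], ]
    expect_equal(row$total_effort, m$total_effort)
    expect_equal(row$bottom_prca_rate, m$bottom_prca_rate)
  }
})
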