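# Synthetic trip generator: condition template, dive synthesis, cohort
# structure, determinism.

test_that("condition template is piecewise linear through its anchors", {
  p <- generator_params("juvenile", seed = 1)
  off <- list(dr_init = 0.15, dr_min = -0.25, dr_peak = 0.05,
              phase1_end = 50, phase2_end = 100, phase3_slope = -0.0035,
              switch_day = NA)
  expect_equal(condition_model(0, p, off), 0.15)
  # midpoint of phase 1 is the mean of its endpoint values
  expect_equal(condition_model(25, p, off),
               mean(c(condition_model(0, p, off),
                      condition_model(50, p, off))))
  expect_equal(condition_model(50, p, off), -0.25)
  expect_equal(condition_model(100, p, off), 0.05)
  # degenerate flat trajectory
  flat <- list(dr_init = 0.1, dr_min = 0.1, dr_peak = 0.1,
               phase1_end = 50, phase2_end = 100, phase3_slope = 0,
               switch_day = NA)
  expect_equal(condition_model(c(0, 10, 75, 200), p, flat), rep(0.1, 4))
  # three-phase shape: down, up, down (to a floor)
  days <- 0:200
  dr <- condition_model(days, p, off)
  expect_true(all(diff(dr[days <= 50]) < 0))
  expect_true(all(diff(dr[days >= 50 & days <= 100]) > 0))
  expect_true(all(diff(dr[days >= 100]) <= 0))
})

test_that("switchers cross zero at their drawn switch day", {
  p <- generator_params("juvenile", seed = 5)
  set.seed(2)
  for (r in 1:20) {
    off <- draw_condition_offsets(p, positive_init = TRUE, switcher = TRUE)
    s <- off$switch_day
    expect_lt(condition_model(s - 0.5, p, off), 0)
    expect_gt(condition_model(s + 0.5, p, off), 0)
  }
})

test_that("noise-free drift dive carries dr_true exactly", {
  p <- generator_params("juvenile", seed = 3, drift_noise_sd = 0,
                        drift_dive_prob = 1)
  set.seed(1)
  d <- simulate_dive(30, -0.12, p)
  seg <- d$segments
  rate <- (seg$depth_start_m[2] - seg$depth_end_m[2]) /
    (seg$t_end_s[2] - seg$t_start_s[2])
  expect_equal(rate, -0.12)
  # passive segment: low effort, no PrCA, >= 40% of the dive, deep start
  expect_lt(seg$effort_sum[2] / (seg$t_end_s[2] - seg$t_start_s[2]), 4)
  expect_equal(seg$prca_s[2], 0)
  expect_gte((seg$t_end_s[2] - seg$t_start_s[2]) / d$duration_s, 0.40)
  expect_gt(seg$depth_start_m[2], 65)
})

test_that("dr_true outside the physical band is rejected", {
  p <- generator_params("juvenile", seed = 1)
  expect_error(simulate_dive(10, -0.31, p), "physical drift band")
  expect_error(simulate_dive(10, 0.60, p), "physical drift band")
})

test_that("dive profiles are physical", {
  p <- generator_params("juvenile", seed = 4)
  set.seed(9)
  for (r in 1:20) {
    d <- simulate_dive(runif(1, 0, 300), runif(1, -0.28, 0.5), p)
    expect_true(all(d$depth >= 0))
    expect_lt(d$depth[1], 5)
    expect_lt(d$depth[length(d$depth)], 5)
    expect_equal(length(d$depth), d$duration_s + 1L)
    # segments partition [0, duration]
    expect_equal(d$segments$t_start_s, c(0, d$segments$t_end_s[1:2]))
    expect_equal(d$segments$t_end_s[3], d$duration_s)
  }
})

test_that("single-day schedule yields one dive per interval", {
  p <- generator_params("juvenile", seed = 2, n_individuals = 1L,
                        trip_days_max = 1, tag_end_min = 1,
                        tag_death_frac = 0)
  rec <- simulate_individual(p, 1, level = "segment")
  expect_equal(nrow(rec$dives), 12L)  # 24 h / 2 h
})

test_that("cohorts are deterministic; individual streams are independent", {
  p <- small_juvenile_params(seed = 31, n = 3, days = 40)
  c1 <- simulate_cohort(p, level = "segment")
  c2 <- simulate_cohort(p, level = "segment")
  expect_identical(serialize(unclass(c1), NULL), serialize(unclass(c2), NULL))
  # an individual's record depends only on its index, params and role,
  # not on whether the rest of the cohort was simulated first
  groups <- divekit:::.cohort_groups(p)
  solo <- simulate_individual(p, 2, groups[[2]], level = "segment")
  expect_identical(solo$dives, c1[[2]]$dives)
  expect_identical(solo$segments_true, c1[[2]]$segments_true)
  # and is unchanged by the cohort-size field itself
  p5 <- small_juvenile_params(seed = 31, n = 5, days = 40)
  solo5 <- simulate_individual(p5, 2, groups[[2]], level = "segment")
  expect_identical(solo5$dives, c1[[2]]$dives)
})

test_that("profile- and segment-level simulation agree on shared fields", {
  p <- small_juvenile_params(seed = 13, n = 2, days = 25)
  cs <- simulate_cohort(p, level = "segment")
  cp <- simulate_cohort(p, level = "profile")
  for (i in 1:2) {
    expect_identical(cs[[i]]$segments_true, cp[[i]]$segments_true)
    expect_identical(cs[[i]]$dives[c("dive_id", "day", "duration_s",
                                     "surface_s", "dr_true")],
                     cp[[i]]$dives[c("dive_id", "day", "duration_s",
                                     "surface_s", "dr_true")])
    # 1-Hz profile is consistent with the true segment corners
    pr <- cp[[i]]$profiles[[1]]
    seg <- cp[[i]]$segments_true[cp[[i]]$segments_true$dive_id ==
                                   cp[[i]]$dives$dive_id[1], ]
    expect_equal(pr[seg$t_end_s[1] + 1L], seg$depth_end_m[1])
    expect_equal(pr[seg$t_end_s[2] + 1L], seg$depth_end_m[2])
  }
})

test_that("default cohort reproduces the study design structure", {
  p <- generator_params("juvenile", seed = 1)
  groups <- divekit:::.cohort_groups(p)
  expect_equal(sum(vapply(groups, `[[`, TRUE, "dead")), 8L)
  expect_equal(sum(vapply(groups, `[[`, TRUE, "positive_init")), 17L)
  expect_equal(sum(vapply(groups, `[[`, TRUE, "switcher")), 9L)
  # switchers are all survivors
  expect_true(all(!vapply(groups, `[[`, TRUE, "dead")[
    vapply(groups, `[[`, TRUE, "switcher")]))
})

test_that("dives never overlap haul-outs and truth is always attached", {
  p <- small_juvenile_params(seed = 17, n = 3, days = 150)
  co <- simulate_cohort(p, level = "segment")
  for (rec in co) {
    expect_false(is.null(rec$truth$daily))
    if (nrow(rec$haul_outs)) {
      for (k in seq_len(nrow(rec$haul_outs)))
        expect_false(any(rec$dives$day >= rec$haul_outs$start_day[k] &
                           rec$dives$day < rec$haul_outs$end_day[k]))
    }
  }
})

test_that("parameter validation rejects bad inputs", {
  expect_error(generator_params("juvenile", drift_dive_prob = 1.4),
               "probabilities")
  expect_error(generator_params("juvenile", dive_dur_sd = -1),
               "standard deviations")
  expect_error(generator_params("juvenile", dive_interval = 0),
               "dive_interval")
  expect_error(generator_params("juvenile", not_a_param = 1), "unknown")
})
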