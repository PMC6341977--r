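# Programmatic fixtures shared across the test files.

# Random noise-free trapezoidal 1-Hz profile with corners on the sample
# grid: descend to z1, slope across the bottom to z2, ascend to the
# surface. For such profiles the greedy broken-stick selection and the
# global minimax optimum coincide (unique zero-error interior pair).
random_trapezoid_profile <- function(n = 200L) {
  repeat {
    c1 <- sample(20:80, 1)
    c2 <- sample((c1 + 20):(n - 20), 1)
    z1 <- runif(1, 80, 400)
    z2 <- z1 + runif(1, -60, 60)
    if (abs(z1 - z2) > 5) break
  }
  t <- 0:(n - 1)
  depth <- numeric(n)
  depth[t <= c1] <- z1 * t[t <= c1] / c1
  mid <- t > c1 & t <= c2
  depth[mid] <- z1 + (z2 - z1) * (t[mid] - c1) / (c2 - c1)
  asc <- t > c2
  depth[asc] <- z2 * (1 - (t[asc] - c2) / (n - 1 - c2))
  list(depth = depth, corners = c(c1, c2) + 1L)  # corner sample indices
}

# Hand-built dive summary with a single interior segment of chosen
# properties; durations in seconds.
make_dive_summary <- function(rate = -0.12, effort_rate = 1.2,
                              prca_fraction = 0, frac = 0.55,
                              duration = 1000, dive_id = "d1") {
  tb <- round(duration * (1 - frac) / 2)
  te <- duration - tb
  seg <- data.frame(
    dive_id = dive_id, segment_idx = 1:3,
    t_start_s = c(0, tb, te), t_end_s = c(tb, te, duration),
    depth_start_m = c(0, 100, 100 - rate * (te - tb)),
    depth_end_m = c(100, 100 - rate * (te - tb), 0),
    vertical_rate = c(-100 / tb, rate,
                      (100 - rate * (te - tb)) / (duration - te)),
    effort_sum = c(6, effort_rate, 6) * c(tb, te - tb, duration - te),
    effort_rate = c(6, effort_rate, 6),
    prca_fraction = c(0, prca_fraction, 0),
    role = c("descent", "bottom", "ascent"))
  structure(list(
    dive = data.frame(dive_id = dive_id, individual_id = "i1", day = 0,
                      max_depth_m = max(seg$depth_start_m),
                      duration_s = duration, surface_s = 60),
    segments = seg), class = "dive_summary")
}

# Random abstracted dives for filter-equivalence checks: segment values
# drawn to straddle every filter threshold, including exact boundary
# values and null rates.
random_abstracted_dives <- function(n_dives = 100L) {
  dives <- seg_list <- vector("list", n_dives)
  for (i in seq_len(n_dives)) {
    k <- sample(3:5, 1)
    dur <- sample(400:1500, 1)
    cuts <- sort(sample(seq(30, dur - 30, by = 10), k - 1L))
    t0 <- c(0, cuts)
    t1 <- c(cuts, dur)
    rate <- sample(c(stats::runif(1, -0.6, 0.9), 0, -0.3, 0.6,
                     stats::runif(1, -0.29, 0.59)), k, replace = TRUE)
    eff <- sample(c(stats::runif(1, 0, 8), 4, 4.0001,
                    stats::runif(1, 0, 3.9)), k, replace = TRUE)
    prca <- sample(c(0, 0, stats::runif(1, 0, 0.3)), k, replace = TRUE)
    id <- sprintf("rd%05d", i)
    seg_list[[i]] <- data.frame(
      dive_id = id, segment_idx = seq_len(k),
      t_start_s = t0, t_end_s = t1,
      depth_start_m = stats::runif(k, 0, 400),
      depth_end_m = stats::runif(k, 0, 400),
      vertical_rate = rate,
      effort_sum = eff * (t1 - t0), effort_rate = eff,
      prca_fraction = prca,
      role = c("descent", rep("bottom", k - 2L), "ascent"))
    dives[[i]] <- data.frame(dive_id = id, individual_id = "rx", day = i %% 200,
                             max_depth_m = 400, duration_s = dur,
                             surface_s = 60)
  }
  list(dives = do.call(rbind, dives), segments = do.call(rbind, seg_list))
}

# Small juvenile parameter set for fast end-to-end tests.
small_juvenile_params <- function(seed = 7L, n = 4L, days = 60) {
  generator_params("juvenile", seed = seed, n_individuals = as.integer(n),
                   trip_days_max = days, tag_end_min = days - 1,
                   tag_death_frac = 0)
}
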