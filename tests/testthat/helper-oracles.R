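# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the package's own code paths.

# Exhaustive minimax broken-stick search: over all pairs of interior
# samples (i, j), minimise the maximum vertical deviation of the 3-chord
# reconstruction through (1, i, j, n). Branch-and-bound on the lower bound
# max(dev(1,i), dev(j,n)) keeps it tractable at n = 200.
oracle_broken_stick <- function(depth) {
  n <- length(depth)
  dev_chord <- function(a, b) {
    if (b - a < 2) return(0)
    idx <- (a + 1):(b - 1)
    line <- depth[a] + (depth[b] - depth[a]) * (idx - a) / (b - a)
    max(abs(depth[idx] - line))
  }
  D1 <- vapply(2:(n - 1), function(i) dev_chord(1, i), numeric(1))
  D2 <- vapply(2:(n - 1), function(j) dev_chord(j, n), numeric(1))
  ord_i <- order(D1)
  ord_j <- order(D2)
  best <- Inf
  best_pair <- NULL
  for (ii in ord_i) {
    i <- ii + 1L
    if (D1[ii] >= best) break
    for (jj in ord_j) {
      j <- jj + 1L
      if (D2[jj] >= best) break
      if (j <= i) next
      lb <- max(D1[ii], D2[jj])
      if (lb >= best) next
      err <- max(lb, dev_chord(i, j))
      if (err < best) {
        best <- err
        best_pair <- c(i, j)
      }
    }
  }
  sort(c(1L, best_pair, n))
}

# Straight-line re-implementation of the five-step drift filter for one
# dive: an explicit loop over segments applying each rule in order.
oracle_drift_filter <- function(dive, segments,
                                effort_max = 4, rate_min = -0.3,
                                rate_max = 0.6, null_tol = 1e-6,
                                min_fraction = 0.40) {
  seg <- segments[order(segments$segment_idx), , drop = FALSE]
  k <- nrow(seg)
  kept_rate <- kept_dur <- numeric(0)
  for (s in seq_len(k)) {
    if (s == 1 || s == k) next                       # step 1: transit
    if (seg$prca_fraction[s] > 0) next               # step 2: PrCA
    if (seg$effort_rate[s] > effort_max) next        # step 3: effort
    rate <- seg$vertical_rate[s]
    if (rate < rate_min || rate > rate_max) next     # step 4a: speed band
    if (abs(rate) < null_tol) next                   # step 4b: null speed
    dur <- seg$t_end_s[s] - seg$t_start_s[s]
    if (dur < min_fraction * dive$duration_s) next   # step 5: duration
    kept_rate <- c(kept_rate, rate)
    kept_dur <- c(kept_dur, dur)
  }
  if (!length(kept_rate)) return(NA_real_)
  out <- sum(kept_rate * kept_dur) / sum(kept_dur)
  if (abs(out) < null_tol) NA_real_ else out
}

# Dive metrics recomputed directly from a raw profile + accel table,
# bypassing the abstraction structures.
oracle_dive_metrics <- function(depth, accel, surface_s) {
  n <- length(depth)
  dur <- n - 1L
  bot <- accel[2, ]
  list(max_depth_m = max(depth),
       duration_min = dur / 60,
       surface_min = surface_s / 60,
       total_effort = accel$effort_sum[1] + accel$effort_sum[3],
       bottom_prca_rate = bot$prca_s / (bot$t_end_s - bot$t_start_s))
}
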