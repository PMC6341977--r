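# Five-step drift-segment filter and per-dive drift-rate estimation.
# Drift rate (m/s, upward positive) is the body-condition proxy: fatter
# seals sink more slowly or rise during the passive phase of drift dives.

#' Drift-filter thresholds
#'
#' @param effort_max maximum swimming-effort rate of a passive segment
#'   (m/s^3); segments exceeding it are removed.
#' @param rate_min,rate_max physical vertical-speed band (m/s); rates
#'   outside `[rate_min, rate_max]` are removed.
#' @param null_tol segments with |rate| below this are treated as null
#'   vertical speed (resting on the sea floor) and removed.
#' @param min_fraction minimum fraction of total dive time a drift segment
#'   must last.
#' @param min_depth optional minimum start depth of a drift segment (m);
#'   `NULL` (default) disables the depth rule, which the filter treats as
#'   rationale rather than a criterion.
#' @return named list of thresholds.
#' @export
drift_filter_control <- function(effort_max = 4, rate_min = -0.3,
                                 rate_max = 0.6, null_tol = 1e-6,
                                 min_fraction = 0.40, min_depth = NULL) {
  list(effort_max = effort_max, rate_min = rate_min, rate_max = rate_max,
       null_tol = null_tol, min_fraction = min_fraction,
       min_depth = min_depth)
}

#' Five-step drift filter for one abstracted dive
#'
#' Applies, in order: (1) remove the first (descent) and last (ascent)
#' segments; (2) remove segments with any detected PrCA behaviour;
#' (3) remove segments whose swimming-effort rate exceeds 4 m/s^3;
#' (4) remove segments whose vertical rate lies outside [-0.3, 0.6] m/s or
#' is null (resting on the sea floor); (5) remove segments lasting less
#' than 40% of the total dive time. If exactly one segment survives its
#' vertical rate is the dive's drift rate; if several survive, their
#' duration-weighted mean is returned.
#'
#' @param summary a `dive_summary` from [abstract_dive()] (>= 3 segments).
#' @param control thresholds from [drift_filter_control()].
#' @return one-row data.frame (`dive_id`, `day`, `drift_rate`, `fraction`)
#'   or `NULL` when no segment survives -- a valid outcome, not an error.
#' @export
filter_drift_segments <- function(summary, control = drift_filter_control()) {
  stopifnot(nrow(summary$segments) >= 3)
  est <- drift_estimates(summary$dive, summary$segments, control)
  if (nrow(est) == 0L) NULL else est
}

#' Drift-rate estimates for stacked abstracted dives
#'
#' Vectorised application of the five-step filter (see
#' [filter_drift_segments()]) across a cohort's abstracted dives. Per-step
#' drop counts are attached as attribute `"drops"` for provenance.
#'
#' @param dives,segments stacked tables from [abstract_cohort()].
#' @param control thresholds from [drift_filter_control()].
#' @return data.frame with one row per dive retaining a drift segment:
#'   `individual_id`, `dive_id`, `day`, `drift_rate` (m/s), `fraction`
#'   (surviving segment duration / dive duration).
#' @export
drift_estimates <- function(dives, segments, control = drift_filter_control()) {
  ct <- control
  seg <- segments
  ord <- order(match(seg$dive_id, dives$dive_id), seg$segment_idx)
  seg <- seg[ord, , drop = FALSE]
  nseg <- tabulate(match(seg$dive_id, dives$dive_id), nbins = nrow(dives))
  dive_dur <- dives$duration_s[match(seg$dive_id, dives$dive_id)]
  last_idx <- nseg[match(seg$dive_id, dives$dive_id)]
  segdur <- seg$t_end_s - seg$t_start_s

  keep1 <- seg$segment_idx > 1L & seg$segment_idx < last_idx
  keep2 <- keep1 & seg$prca_fraction <= 0
  keep3 <- keep2 & seg$effort_rate <= ct$effort_max
  keep4 <- keep3 & seg$vertical_rate >= ct$rate_min &
    seg$vertical_rate <= ct$rate_max &
    abs(seg$vertical_rate) >= ct$null_tol
  keep5 <- keep4 & segdur >= ct$min_fraction * dive_dur
  if (!is.null(ct$min_depth))
    keep5 <- keep5 & pmin(seg$depth_start_m, seg$depth_end_m) >= ct$min_depth

  drops <- c(step1_transit = sum(!keep1),
             step2_prca = sum(keep1 & !keep2),
             step3_effort = sum(keep2 & !keep3),
             step4_speed = sum(keep3 & !keep4),
             step5_fraction = sum(keep4 & !keep5))

  s <- seg[keep5, , drop = FALSE]
  sdur <- segdur[keep5]
  if (nrow(s) == 0L) {
    out <- data.frame(individual_id = character(0), dive_id = character(0),
                      day = numeric(0), drift_rate = numeric(0),
                      fraction = numeric(0))
    attr(out, "drops") <- drops
    return(out)
  }
  wsum <- rowsum(s$vertical_rate * sdur, s$dive_id, reorder = FALSE)
  dsum <- rowsum(sdur, s$dive_id, reorder = FALSE)
  rate <- wsum[, 1] / dsum[, 1]
  id <- rownames(wsum)
  mi <- match(id, dives$dive_id)
  out <- data.frame(
    individual_id = if ("individual_id" %in% names(dives))
      dives$individual_id[mi] else NA_character_,
    dive_id = id, day = dives$day[mi],
    drift_rate = rate,
    fraction = dsum[, 1] / dives$duration_s[mi]
  )
  # a duration-weighted mean of mixed-sign rates can itself be null
  out <- out[abs(out$drift_rate) >= ct$null_tol, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drops") <- drops
  out
}

#' Daily drift-rate series with smoothed trajectory
#'
#' Collapses one individual's drift estimates to a per-day median, on the
#' full day grid from 0 to the last day observed (days without estimates
#' stay missing), and smooths with a centred rolling median (default
#' window 7 days, requiring at least `min_obs` daily values in the
#' window).
#'
#' @param estimates data.frame from [drift_estimates()], one individual.
#' @param window rolling-median window in days (centred).
#' @param min_obs minimum daily values in the window to emit a smoothed
#'   value.
#' @param end_day optional last day of the grid (defaults to the last
#'   day with an estimate).
#' @return data.frame of class `condition_series`: `day`, `dr_raw`
#'   (daily median), `dr_smooth`. Empty input gives an empty series.
#' @export
daily_drift_series <- function(estimates, window = 7L, min_obs = 3L,
                               end_day = NULL) {
  if (nrow(estimates) == 0L) {
    out <- data.frame(day = integer(0), dr_raw = numeric(0),
                      dr_smooth = numeric(0))
    class(out) <- c("condition_series", "data.frame")
    return(out)
  }
  d <- floor(estimates$day)
  last <- if (is.null(end_day)) max(d) else floor(end_day)
  days <- 0:last
  med <- tapply(estimates$drift_rate, factor(d, levels = days), stats::median)
  raw <- as.numeric(med)
  sm <- .rolling_median(raw, window = window, min_obs = min_obs)
  out <- data.frame(day = days, dr_raw = raw, dr_smooth = sm)
  if (!is.null(estimates$individual_id) && nrow(estimates))
    attr(out, "individual_id") <- estimates$individual_id[1]
  class(out) <- c("condition_series", "data.frame")
  out
}

# Centred rolling median tolerating missing values; emits NA where fewer
# than `min_obs` observations fall inside the window.
.rolling_median <- function(x, window = 7L, min_obs = 3L) {
  n <- length(x)
  half <- window %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - half):min(n, i + half)]
    w <- w[!is.na(w)]
    if (length(w) >= min_obs) out[i] <- stats::median(w)
  }
  out
}
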