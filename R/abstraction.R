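# Broken-stick abstraction of 1-Hz dive profiles into descent/bottom/ascent
# segment summaries, mirroring the on-board processing of satellite relay
# dive-and-accelerometer tags.

#' Iterative broken-stick point selection
#'
#' Starting from the two profile endpoints, repeatedly adds the sample with
#' the largest vertical distance from the current piecewise-linear
#' reconstruction until `n_points` inflection points are retained. Ties go
#' to the earliest sample.
#'
#' @param depth numeric vector of 1-Hz depth samples (m, positive down).
#' @param n_points total points retained including both endpoints
#'   (default 4, giving three segments).
#' @return integer vector of retained sample indices, sorted.
#' @export
broken_stick_points <- function(depth, n_points = 4L) {
  n <- length(depth)
  stopifnot(n >= n_points, n_points >= 3)
  t <- seq_len(n)
  pts <- c(1L, n)
  while (length(pts) < n_points) {
    recon <- stats::approx(t[pts], depth[pts], xout = t)$y
    dev <- abs(depth - recon)
    pts <- sort(c(pts, which.max(dev)))
  }
  pts
}

# Collapse >3 segments to descent/bottom/ascent roles: descent = contiguous
# leading segments sinking faster than 0.1 m/s, ascent = contiguous trailing
# segments rising faster than 0.1 m/s, bottom = remainder (ties to bottom).
.assign_roles <- function(vertical_rate) {
  k <- length(vertical_rate)
  if (k == 3L) return(c("descent", "bottom", "ascent"))
  roles <- rep("bottom", k)
  i <- 1L
  while (i < k && vertical_rate[i] < -0.1) { roles[i] <- "descent"; i <- i + 1L }
  j <- k
  while (j > i && vertical_rate[j] > 0.1) { roles[j] <- "ascent"; j <- j - 1L }
  if (all(roles == "bottom")) { roles[1] <- "descent"; roles[k] <- "ascent" }
  roles
}

#' Abstract one dive profile into a segment summary
#'
#' Applies the broken-stick selection to a 1-Hz depth profile and maps the
#' accelerometer segment summaries (swimming-effort sums, PrCA seconds)
#' onto the abstracted segments by duration-weighted time overlap. The
#' reported maximum depth is the raw profile maximum, not the maximum of
#' the reconstruction.
#'
#' @param depth numeric 1-Hz depth samples, t = 0..duration; the profile
#'   must start and end near the surface (< 5 m).
#' @param accel data.frame of input accelerometer summaries with columns
#'   `t_start_s`, `t_end_s`, `effort_sum`, `prca_s`, spanning the profile.
#' @param dive_id,individual_id,day,surface_s dive metadata carried through.
#' @param n_points broken-stick points retained (default 4 = 3 segments).
#' @return a `dive_summary`: list with `dive` (one-row data.frame:
#'   `dive_id`, `individual_id`, `day`, `max_depth_m`, `duration_s`,
#'   `surface_s`) and `segments` (one row per segment: times, start/end
#'   depths, `vertical_rate` m/s upward-positive, `effort_sum`,
#'   `effort_rate` m/s^3, `prca_fraction`, `role`). Returns `NULL`,
#'   with a message, for profiles shorter than 10 samples or never
#'   exceeding 15 m (not a dive).
#' @export
abstract_dive <- function(depth, accel = NULL, dive_id = "dive-1",
                          individual_id = NA_character_, day = NA_real_,
                          surface_s = NA_real_, n_points = 4L) {
  n <- length(depth)
  if (n < 10L || max(depth) <= 15) {
    message("profile '", dive_id, "' rejected as non-dive (",
            if (n < 10L) "shorter than 10 s" else "never exceeds 15 m", ")")
    return(NULL)
  }
  if (depth[1] >= 5 || depth[n] >= 5)
    stop("dive profile must start and end at depth < 5 m")
  pts <- broken_stick_points(depth, n_points)
  k <- length(pts) - 1L
  t <- pts - 1L               # sample times, 0-based
  t_start <- t[-length(t)]
  t_end <- t[-1]
  d_start <- depth[pts[-length(pts)]]
  d_end <- depth[pts[-1]]
  vrate <- (d_start - d_end) / (t_end - t_start)  # upward positive
  eff <- prca <- numeric(k)
  if (!is.null(accel) && nrow(accel)) {
    for (j in seq_len(k)) {
      ov <- pmax(0, pmin(t_end[j], accel$t_end_s) -
                    pmax(t_start[j], accel$t_start_s))
      w <- ov / (accel$t_end_s - accel$t_start_s)
      eff[j] <- sum(w * accel$effort_sum)
      prca[j] <- sum(w * accel$prca_s)
    }
  }
  seg <- data.frame(
    dive_id = dive_id, segment_idx = seq_len(k),
    t_start_s = t_start, t_end_s = t_end,
    depth_start_m = d_start, depth_end_m = d_end,
    vertical_rate = vrate,
    effort_sum = eff,
    effort_rate = eff / (t_end - t_start),
    prca_fraction = prca / (t_end - t_start),
    role = .assign_roles(vrate)
  )
  structure(list(
    dive = data.frame(dive_id = dive_id, individual_id = individual_id,
                      day = day, max_depth_m = max(depth),
                      duration_s = n - 1L, surface_s = surface_s),
    segments = seg
  ), class = "dive_summary")
}

#' Abstract every dive of a trip record (or plain profile list)
#'
#' @param record a `trip_record` from [simulate_individual()] (profile
#'   level), or a list with elements `dives`, `profiles`, `segments_true`
#'   following the same schema.
#' @param n_points passed to [abstract_dive()].
#' @return list with two data.frames, `dives` and `segments`, in the same
#'   schema as [abstract_dive()] output, stacked over dives.
#' @export
abstract_record <- function(record, n_points = 4L) {
  dv <- record$dives
  if (is.null(record$profiles))
    stop("record carries no 1-Hz profiles; simulate with level = 'profile'")
  acc_split <- split(record$segments_true, record$segments_true$dive_id)
  n <- nrow(dv)
  dive_rows <- vector("list", n)
  seg_rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- abstract_dive(record$profiles[[dv$dive_id[i]]],
                       accel = acc_split[[dv$dive_id[i]]],
                       dive_id = dv$dive_id[i],
                       individual_id = dv$individual_id[i],
                       day = dv$day[i], surface_s = dv$surface_s[i],
                       n_points = n_points)
    if (is.null(s)) next
    dive_rows[[i]] <- s$dive
    seg_rows[[i]] <- s$segments
  }
  list(dives = do.call(rbind, dive_rows),
       segments = do.call(rbind, seg_rows))
}

# Segment-level records skip the 1-Hz reconstruction: the generator's true
# segments are taken as the abstraction (the two coincide for noise-free
# piecewise-linear profiles).
.record_summaries <- function(record, n_points = 4L) {
  if (!is.null(record$profiles)) return(abstract_record(record, n_points))
  seg <- record$segments_true
  dur <- seg$t_end_s - seg$t_start_s
  seg$vertical_rate <- (seg$depth_start_m - seg$depth_end_m) / dur
  seg$effort_rate <- seg$effort_sum / dur
  seg$prca_fraction <- seg$prca_s / dur
  seg$role <- c("descent", "bottom", "ascent")[seg$segment_idx]
  seg$prca_s <- NULL
  dv <- record$dives
  list(
    dives = data.frame(dive_id = dv$dive_id, individual_id = dv$individual_id,
                       day = dv$day, max_depth_m = dv$max_depth_m,
                       duration_s = dv$duration_s, surface_s = dv$surface_s),
    segments = seg[c("dive_id", "segment_idx", "t_start_s", "t_end_s",
                     "depth_start_m", "depth_end_m", "vertical_rate",
                     "effort_sum", "effort_rate", "prca_fraction", "role")]
  )
}

#' Abstract a whole cohort
#'
#' @param cohort a `trip_cohort` from [simulate_cohort()].
#' @param n_points passed to [abstract_dive()].
#' @return list of data.frames `dives` and `segments` stacked over
#'   individuals.
#' @export
abstract_cohort <- function(cohort, n_points = 4L) {
  parts <- lapply(cohort, .record_summaries, n_points = n_points)
  list(dives = do.call(rbind, c(lapply(parts, `[[`, "dives"),
                                make.row.names = FALSE)),
       segments = do.call(rbind, c(lapply(parts, `[[`, "segments"),
                                   make.row.names = FALSE)))
}

#' Per-dive metrics in reporting units
#'
#' Converts an abstracted dive to the analysis metrics: durations in
#' minutes, total swimming effort summed over the transit (descent +
#' ascent) segments, and the bottom-segment PrCA rate.
#'
#' @param summary a `dive_summary` from [abstract_dive()].
#' @return one-row data.frame with `max_depth_m`, `duration_min`,
#'   `surface_min`, `total_effort`, `bottom_prca_rate`.
#' @export
dive_metrics <- function(summary) {
  seg <- summary$segments
  data.frame(
    dive_id = summary$dive$dive_id,
    max_depth_m = summary$dive$max_depth_m,
    duration_min = summary$dive$duration_s / 60,
    surface_min = summary$dive$surface_s / 60,
    total_effort = sum(seg$effort_sum[seg$role %in% c("descent", "ascent")]),
    bottom_prca_rate = {
      b <- seg$prca_fraction[seg$role == "bottom"]
      if (length(b)) stats::weighted.mean(
        b, (seg$t_end_s - seg$t_start_s)[seg$role == "bottom"]) else NA_real_
    }
  )
}

# Vectorised dive metrics over stacked dives/segments tables.
.metrics_table <- function(dives, segments) {
  transit <- segments$role %in% c("descent", "ascent")
  te <- rowsum(segments$effort_sum * transit, segments$dive_id, reorder = FALSE)
  bot <- segments$role == "bottom"
  dur <- segments$t_end_s - segments$t_start_s
  pr_num <- rowsum(segments$prca_fraction * dur * bot, segments$dive_id,
                   reorder = FALSE)
  pr_den <- rowsum(dur * bot, segments$dive_id, reorder = FALSE)
  m <- data.frame(dive_id = rownames(te), total_effort = te[, 1],
                  bottom_prca_rate = ifelse(pr_den[, 1] > 0,
                                            pr_num[, 1] / pr_den[, 1],
                                            NA_real_))
  out <- merge(dives, m, by = "dive_id", sort = FALSE)
  out$duration_min <- out$duration_s / 60
  out$surface_min <- out$surface_s / 60
  out
}
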