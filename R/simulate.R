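# Synthetic trip generator: 1-Hz dive profiles, segment-level accelerometer
# summaries, surface intervals and haul-outs, with known generating truth.

# --- ontogeny curves ------------------------------------------------------

.depth_mean <- function(day, p) {
  if (p$age_class == "adult") return(rep(p$adult_depth_mean, length(day)))
  stats::approx(x = c(0, 50, p$month8_day, 1e6),
                y = c(p$depth_mean_day0, p$depth_mean_day50,
                      p$depth_mean_month8, p$depth_mean_month8),
                xout = day, rule = 2)$y
}

.depth_sd <- function(day, p) {
  if (p$age_class == "adult") return(rep(p$adult_depth_sd, length(day)))
  stats::approx(x = c(0, 50, p$month8_day, 1e6),
                y = c(p$depth_sd_day0, p$depth_sd_day50,
                      p$depth_sd_month8, p$depth_sd_month8),
                xout = day, rule = 2)$y
}

.dur_mean <- function(day, p) {
  if (p$dive_dur_ramp == 0) return(rep(p$dive_dur_mean, length(day)))
  p$dive_dur_mean +
    p$dive_dur_ramp * (pmin(day, p$dive_dur_ramp_days) / p$dive_dur_ramp_days - 0.5)
}

.prca_mean <- function(day, p) {
  p$prca_adult_scale + (p$prca_juv_scale - p$prca_adult_scale) *
    pmax(0, 1 - day / p$prca_decay_day)
}

# --- vectorised per-dive synthesis ---------------------------------------

# Draw all per-dive quantities for dives starting at fractional days
# `day_frac` with true drift rates `dr_true`. One canonical draw order,
# independent of the drift/active branch, keeps streams stable.
.draw_dive_scalars <- function(p, day_frac, dr_true,
                               force_drift = NA) {
  n <- length(day_frac)
  if (n == 0L) return(NULL)
  z   <- pmax(stats::rnorm(n, .depth_mean(day_frac, p), .depth_sd(day_frac, p)),
              p$depth_min)
  dur_noise <- stats::rnorm(n, 0, p$dive_dur_sd)   # min
  Ts  <- pmax(.dur_mean(day_frac, p) + dur_noise, p$dive_dur_min) * 60
  is_drift <- stats::runif(n) < p$drift_dive_prob
  if (!is.na(force_drift)) is_drift <- rep(as.logical(force_drift), n)
  rd  <- stats::runif(n, p$vr_min, p$vr_max)
  ra  <- stats::runif(n, p$vr_min, p$vr_max)
  dfrac <- stats::runif(n, p$drift_frac_min, p$drift_frac_max)
  drnoise <- if (p$drift_noise_sd > 0) stats::rnorm(n, 0, p$drift_noise_sd)
             else numeric(n)
  u_mind  <- stats::runif(n, 0, 10)
  amp  <- stats::runif(n, 1, p$wiggle_amp_max)
  kcyc <- sample(1:3, n, replace = TRUE)
  eff_noise_d <- stats::rnorm(n, 0, p$effort_sd)
  eff_noise_b <- stats::rnorm(n, 0, p$effort_sd)
  eff_noise_a <- stats::rnorm(n, 0, p$effort_sd)
  drift_eff <- stats::runif(n, p$drift_effort_min, p$drift_effort_max)
  fr <- pmax(0, stats::rnorm(n, .prca_mean(day_frac, p), p$prca_sd))
  surf_noise <- stats::rnorm(n, 0, p$surf_noise_sd)
  is_ext   <- stats::runif(n) < p$extended_surf_prob
  ext_extra <- stats::rexp(n, rate = 1 / p$extended_surf_exp_mean)

  # active-dive geometry (trapezoid with bottom wiggles). Bottom time is
  # drawn and duration emerges as transit + bottom, so duration and depth
  # are positively coupled (deeper dives last longer) without the
  # truncation artefacts that independent duration draws would create;
  # the expected duration on a given day stays at the ontogeny mean.
  mean_transit_s <- .depth_mean(day_frac, p) *
    2 * log(p$vr_max / p$vr_min) / (p$vr_max - p$vr_min)
  t_desc <- pmax(1, round(z / rd))
  t_asc  <- pmax(1, round(z / ra))
  t_bot  <- pmax(p$min_bottom_s,
                 round((.dur_mean(day_frac, p) + dur_noise) * 60 -
                         mean_transit_s))
  z0 <- z
  z1 <- z

  # drift-dive geometry: bottom replaced by a passive segment at dr_true
  # (+noise), starting below `drift_min_depth`, lasting >= ~45% of the dive
  if (any(is_drift)) {
    i <- which(is_drift)
    dr_seg <- dr_true[i] + drnoise[i]
    D <- pmax(30, round(dfrac[i] * Ts[i]))
    # drift dives are rest/digestion dives at mid-water depths: the
    # passive phase starts below drift_min_depth but not at the (possibly
    # much deeper) foraging depth
    z0d <- pmax(pmin(z[i], p$drift_start_max),
                p$drift_min_depth + u_mind[i])
    for (it in 1:3) {
      z0d <- pmax(z0d, ifelse(dr_seg > 0, dr_seg * D + 15, 0))
      z1d <- z0d - dr_seg * D
      td  <- pmax(1, round(z0d / rd[i]))
      ta  <- pmax(1, round(pmax(z1d, 1) / ra[i]))
      bad <- D / (td + D + ta) < 0.43
      if (!any(bad)) break
      D[bad] <- ceiling(0.80 * (td + ta))[bad]
    }
    t_desc[i] <- td; t_asc[i] <- ta; t_bot[i] <- D
    z0[i] <- z0d; z1[i] <- z1d
    amp[i] <- 0
  }
  duration <- t_desc + t_bot + t_asc

  eff_desc <- p$effort_neutral_min + p$effort_buoyancy_coef * abs(dr_true) +
    eff_noise_d
  eff_asc  <- p$effort_neutral_min + p$effort_buoyancy_coef * abs(dr_true) +
    eff_noise_a
  eff_bot  <- ifelse(is_drift, drift_eff,
                     p$effort_neutral_min +
                       p$effort_buoyancy_coef * abs(dr_true) + eff_noise_b)
  fr[is_drift] <- 0
  prca_s <- fr * t_bot

  total_transit_effort <- eff_desc * t_desc + eff_asc * t_asc
  surf_min <- p$surf_base + p$surf_effort_coef * total_transit_effort -
    p$surf_prca_coef * fr + surf_noise
  surf_s <- pmax(p$surf_floor_s, surf_min * 60)
  surf_s[is_ext] <- (p$extended_surf_min + ext_extra[is_ext]) * 60

  data.frame(
    day = day_frac, dr_true = dr_true, is_drift = is_drift,
    t_desc = t_desc, t_bot = t_bot, t_asc = t_asc,
    duration_s = duration, surface_s = surf_s,
    z0 = z0, z1 = z1, amp = amp, kcyc = kcyc,
    eff_desc = eff_desc, eff_bot = eff_bot, eff_asc = eff_asc,
    prca_fr = fr, prca_s = prca_s
  )
}

# True segment table (3 rows per dive) from the scalar draws.
.scalars_to_segments <- function(sc) {
  n <- nrow(sc)
  b1 <- sc$t_desc
  b2 <- sc$t_desc + sc$t_bot
  Tt <- sc$duration_s
  data.frame(
    dive_row = rep(seq_len(n), each = 3L),
    segment_idx = rep(1:3, n),
    t_start_s = as.vector(rbind(0, b1, b2)),
    t_end_s   = as.vector(rbind(b1, b2, Tt)),
    depth_start_m = as.vector(rbind(0, sc$z0, sc$z1)),
    depth_end_m   = as.vector(rbind(sc$z0, sc$z1, 0)),
    effort_sum = as.vector(rbind(sc$eff_desc * sc$t_desc,
                                 sc$eff_bot * sc$t_bot,
                                 sc$eff_asc * sc$t_asc)),
    prca_s = as.vector(rbind(0, sc$prca_s, 0))
  )
}

# 1-Hz depth samples (t = 0..duration) for one dive's scalar row.
.build_profile <- function(sc) {
  desc <- sc$z0 * (0:sc$t_desc) / sc$t_desc
  u <- (1:sc$t_bot) / sc$t_bot
  bot <- if (sc$is_drift || sc$amp == 0) {
    sc$z0 + (sc$z1 - sc$z0) * u
  } else {
    sc$z0 + sc$amp * sin(2 * pi * sc$kcyc * u)
  }
  asc <- sc$z1 * (1 - (1:sc$t_asc) / sc$t_asc)
  c(desc, bot, asc)
}

#' Simulate a single dive record
#'
#' Generates one dive -- 1-Hz depth samples, per-segment accelerometer
#' summaries (lateral-axis swimming-effort sums and PrCA seconds) and the
#' post-dive surface duration -- for a given day of the trip and true drift
#' rate. With probability `drift_dive_prob` (or always, if
#' `force_drift = TRUE`) the bottom phase is replaced by a passive drift
#' segment whose vertical rate is `dr_true` plus noise.
#'
#' @param day day since departure (may be fractional).
#' @param dr_true true drift rate in m/s; must lie inside the physical
#'   drift band (-0.3, 0.6).
#' @param params a [generator_params()] object.
#' @param force_drift `NA` (use `drift_dive_prob`), `TRUE` or `FALSE`.
#' @return list with `depth` (numeric, 1-Hz samples at t = 0..duration),
#'   `duration_s`, `surface_s`, `segments` (true segment table with times,
#'   depths, `effort_sum`, `prca_s`) and `is_drift`.
#' @export
simulate_dive <- function(day, dr_true, params, force_drift = NA) {
  stopifnot(day >= 0)
  if (dr_true <= -0.3 || dr_true >= 0.6)
    stop("dr_true = ", dr_true,
         " is outside the physical drift band (-0.3, 0.6) m/s")
  sc <- .draw_dive_scalars(params, day, dr_true, force_drift = force_drift)
  seg <- .scalars_to_segments(sc)
  seg$dive_row <- NULL
  list(depth = .build_profile(sc[1, ]),
       duration_s = sc$duration_s, surface_s = sc$surface_s,
       segments = seg, is_drift = sc$is_drift)
}

# --- individual-level simulation -----------------------------------------

# Juvenile schedule: one recorded dive every `dive_interval` hours,
# skipping haul-out days.
.juvenile_start_times <- function(p, end_day, haul_outs) {
  step <- p$dive_interval * 3600
  if (end_day * 86400 < step) return(numeric(0))
  t0 <- seq(0, end_day * 86400 - step, by = step)
  d <- t0 / 86400
  if (nrow(haul_outs)) {
    for (k in seq_len(nrow(haul_outs)))
      t0 <- t0[!(d >= haul_outs$start_day[k] & d < haul_outs$end_day[k])]
    d <- t0 / 86400
  }
  t0
}

.simulate_dives_juvenile <- function(p, offsets, end_day, haul_outs) {
  t0 <- .juvenile_start_times(p, end_day, haul_outs)
  day_frac <- t0 / 86400
  dr <- condition_model(day_frac, p, offsets)
  sc <- .draw_dive_scalars(p, day_frac, dr)
  sc$t0_s <- t0
  sc
}

# Adult schedule: continuous diving; the next dive starts when the previous
# surface interval ends. Day-wise chunks keep the drawing vectorised.
.simulate_dives_adult <- function(p, offsets, end_day) {
  end_s <- end_day * 86400
  out <- vector("list", ceiling(end_day) + 1L)
  cursor <- 0
  k <- 0L
  typ_cycle <- max(300, 0.6 * p$dive_dur_mean * 60)
  while (cursor < end_s) {
    d <- floor(cursor / 86400)
    day_end <- min((d + 1) * 86400, end_s)
    m <- ceiling((day_end - cursor) / typ_cycle) + 3L
    dr <- condition_model(rep(cursor / 86400, m), p, offsets)
    sc <- .draw_dive_scalars(p, rep(cursor / 86400, m), dr)
    t0 <- cursor + c(0, cumsum(sc$duration_s + sc$surface_s))[seq_len(m)]
    keep <- t0 < day_end & (t0 + sc$duration_s) <= end_s
    if (!any(keep)) break
    sc <- sc[keep, , drop = FALSE]
    sc$t0_s <- t0[keep]
    sc$day <- sc$t0_s / 86400
    k <- k + 1L
    out[[k]] <- sc
    cursor <- sc$t0_s[nrow(sc)] + sc$duration_s[nrow(sc)] +
      sc$surface_s[nrow(sc)]
  }
  do.call(rbind, out[seq_len(k)])
}

#' Simulate one individual's full trip record
#'
#' @param params a [generator_params()] object.
#' @param index individual index within the cohort (drives the
#'   per-individual random stream).
#' @param group list with logicals `dead` (early tag failure),
#'   `positive_init` and `switcher`; defaults describe a surviving,
#'   initially buoyant, switching juvenile (ignored where the age class
#'   makes them moot).
#' @param level `"profile"` (full 1-Hz depth synthesis) or `"segment"`
#'   (segment summaries only; statistically equivalent downstream of the
#'   abstraction and much faster).
#' @return A `trip_record`: list with `individual_id`, `morph`, `dives`,
#'   `segments_true`, `profiles` (or NULL), `haul_outs` and `truth`
#'   (daily true drift rate, template offsets, switch day, end day).
#' @export
simulate_individual <- function(params, index = 1L,
                                group = list(dead = FALSE,
                                             positive_init = TRUE,
                                             switcher = TRUE),
                                level = c("profile", "segment")) {
  p <- params
  level <- match.arg(level)
  if (p$age_class == "adult")
    group <- list(dead = FALSE, positive_init = FALSE, switcher = FALSE)
  set.seed(individual_seed(p$seed, index))
  id <- sprintf("%s%03d", if (p$age_class == "juvenile") "J" else "A", index)

  mass <- max(10, stats::rnorm(1, p$mass_mean, p$mass_sd))
  len  <- max(50, stats::rnorm(1, p$length_mean, p$length_sd))
  deploy_day <- -round(max(0, stats::rnorm(1, 9.7, 6.6)), 1)

  offsets <- draw_condition_offsets(p, positive_init = group$positive_init,
                                    switcher = group$switcher)
  if (isTRUE(group$dead)) {
    end_day <- stats::runif(1, p$tag_death_day_min, p$tag_death_day_max)
  } else {
    end_day <- stats::runif(1, min(p$tag_end_min, p$trip_days_max),
                            p$trip_days_max)
  }

  # one mid-record haul-out for surviving juveniles; duration keyed to the
  # buoyancy sign at return
  haul_outs <- data.frame(start_day = numeric(0), end_day = numeric(0))
  if (p$age_class == "juvenile" && !isTRUE(group$dead)) {
    # the return transit to the colony takes weeks (turning points were
    # hundreds to thousands of km out), so the haul-out starts well after
    # the central-phase peak
    h0 <- if (group$switcher) offsets$phase2_end + stats::runif(1, 15, 40)
          else stats::runif(1, 120, 160)
    if (h0 < end_day - 2) {
      sign_pos <- condition_model(h0, p, offsets) > 0
      hd <- if (sign_pos) stats::rnorm(1, p$haulout_pos_mean, p$haulout_pos_sd)
            else stats::rnorm(1, p$haulout_neg_mean, p$haulout_neg_sd)
      hd <- max(0.5, hd)
      haul_outs <- data.frame(start_day = h0,
                              end_day = min(h0 + hd, end_day))
    }
  }

  sc <- if (is.na(p$dive_interval)) {
    .simulate_dives_adult(p, offsets, end_day)
  } else {
    .simulate_dives_juvenile(p, offsets, end_day, haul_outs)
  }
  n <- nrow(sc)
  dive_id <- sprintf("%s-%05d", id, seq_len(n))

  segs <- .scalars_to_segments(sc)
  segs <- data.frame(dive_id = dive_id[segs$dive_row],
                     segs[setdiff(names(segs), "dive_row")])

  profiles <- NULL
  max_depth <- pmax(sc$z0, sc$z1) + ifelse(sc$is_drift, 0, sc$amp * 0.98)
  if (level == "profile") {
    profiles <- vector("list", n)
    for (i in seq_len(n)) {
      profiles[[i]] <- .build_profile(sc[i, ])
      max_depth[i] <- max(profiles[[i]])
    }
    names(profiles) <- dive_id
  }

  dives <- data.frame(
    dive_id = dive_id, individual_id = id,
    day = sc$day, t0_s = sc$t0_s,
    duration_s = sc$duration_s, surface_s = sc$surface_s,
    max_depth_m = max_depth, is_drift = sc$is_drift,
    dr_true = sc$dr_true
  )

  days <- 0:floor(max(end_day - 1e-9, 0))
  truth_daily <- data.frame(day = days,
                            dr_true = condition_model(days, p, offsets))

  structure(list(
    individual_id = id, age_class = p$age_class,
    morph = data.frame(individual_id = id, age_class = p$age_class,
                       mass_kg = mass, length_cm = len,
                       deploy_day = deploy_day, departure_day = 0),
    dives = dives, segments_true = segs, profiles = profiles,
    haul_outs = haul_outs,
    truth = list(daily = truth_daily, offsets = offsets,
                 switch_day = offsets$switch_day,
                 dead = isTRUE(group$dead), end_day = end_day)
  ), class = "trip_record")
}

#' Simulate a cohort of trip records
#'
#' Simulates `n_individuals` independent individuals from one master seed.
#' Cohort-level structure follows the study design: a fixed fraction of
#' individuals suffer early tag failure (defaults: 8 of 20 juveniles within
#' 100 days), a fixed fraction depart positively buoyant (17 of 20), and a
#' fixed fraction of survivors switch to positive buoyancy during the
#' central phase (9 of 12). Each individual draws from its own sub-stream,
#' so a given (index, role) pair always yields the same record regardless
#' of what else is simulated; the cohort-level role assignment itself
#' depends on `n_individuals` (the counts are fixed fractions of it).
#'
#' @inheritParams simulate_individual
#' @return list of `trip_record`s, class `"trip_cohort"`, with the
#'   generating `params` attached as an attribute.
#' @export
simulate_cohort <- function(params, level = c("profile", "segment")) {
  p <- params
  level <- match.arg(level)
  n <- p$n_individuals
  groups <- .cohort_groups(p)
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    cohort[[i]] <- simulate_individual(p, i, group = groups[[i]],
                                       level = level)
  }
  names(cohort) <- vapply(cohort, `[[`, "", "individual_id")
  structure(cohort, class = "trip_cohort", params = p)
}

# Cohort-level assignment of early tag failure, initial buoyancy sign and
# central-phase switching, drawn from the master seed with fixed counts
# (round(frac * n)) so the default juvenile cohort reproduces the study
# design: 8/20 lost early, 17/20 initially positive, 9/12 survivors switch.
.cohort_groups <- function(p) {
  n <- p$n_individuals
  set.seed(p$seed)
  dead <- rep(FALSE, n)
  nd <- round(p$tag_death_frac * n)
  if (nd > 0) dead[sample.int(n, nd)] <- TRUE
  pos <- rep(FALSE, n)
  np <- round(p$init_pos_frac * n)
  if (np > 0) pos[sample.int(n, np)] <- TRUE
  survivors <- which(!dead)
  sw <- rep(FALSE, n)
  if (length(survivors) && p$switch_frac > 0) {
    k <- round(p$switch_frac * length(survivors))
    if (k > 0) sw[sample(survivors, k)] <- TRUE
  }
  lapply(seq_len(n), function(i)
    list(dead = dead[i], positive_init = pos[i], switcher = sw[i]))
}

#' @export
print.trip_cohort <- function(x, ...) {
  p <- attr(x, "params")
  nd <- sum(vapply(x, function(r) nrow(r$dives), 0))
  cat("<trip_cohort>", length(x), p$age_class, "individuals,",
      nd, "dives, seed", p$seed, "\n")
  invisible(x)
}

#' Cohort morphometrics table
#' @param cohort a `trip_cohort`.
#' @return data.frame with one row per individual.
#' @export
cohort_morphometrics <- function(cohort) {
  do.call(rbind, lapply(cohort, `[[`, "morph"))
}
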