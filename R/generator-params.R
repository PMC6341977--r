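#' Parameter set for the synthetic trip generator
#'
#' Builds and validates the full parameter list controlling the synthetic
#' trip generator. Defaults are calibrated so that a default cohort, pushed
#' through the whole abstraction -> drift-filter -> trajectory -> ADL
#' pipeline, reproduces the cohort statistics reported for first-year
#' juvenile southern elephant seals (and post-breeding adult females)
#' tracked from Kerguelen. Two default sets are provided, selected by
#' `age_class`:
#'
#' * `"juvenile"`: 20 individuals, one recorded dive every 2 h, trips up to
#'   338 days, depth ontogeny from ~60 m at departure to 115 m at day 50 and
#'   227 m at month 8, dive durations ramping around a 12.5 min mean,
#'   three-phase drift-rate (body condition) template with a buoyancy
#'   switch near day 93 for 9 of the 12 survivors, 8 early tag failures.
#' * `"adult"`: 9 post-breeding females recorded continuously for 2-3
#'   months, stationary 474 m mean depth and 18.5 min mean duration,
#'   gradually improving but always negative buoyancy.
#'
#' @param age_class `"juvenile"` or `"adult"`; chooses the default block.
#' @param seed integer master seed; every random draw in the generator
#'   derives from it (per-individual sub-streams, so changing
#'   `n_individuals` does not reshuffle earlier individuals).
#' @param ... named overrides for any parameter listed in Details.
#'
#' @details Units: depths m, durations of dives s internally but parameter
#'   means in min, drift rates m/s (upward positive), swimming effort rate
#'   m/s^3 (lateral-axis acceleration sum scaled by segment duration),
#'   PrCA as a fraction of bottom-segment time, days since departure.
#'
#' Key groups (defaults in parentheses, juvenile / adult):
#' * cohort: `n_individuals` (20/9), `trip_days_max` (338/90),
#'   `dive_interval` hours (2 / `NA` = continuous), `tag_death_frac`
#'   (0.4/0), `tag_death_day_min`/`max` (15/100), `tag_end_min` (150/60).
#' * depth ontogeny: `depth_mean_day0/day50/month8` + SDs, `month8_day`
#'   (240); adults: `adult_depth_mean` (474), `adult_depth_sd` (79).
#' * durations: `dive_dur_mean` min (12.5/18.5), `dive_dur_sd` (5),
#'   `dive_dur_ramp` (6/0) total rise across `dive_dur_ramp_days` (180),
#'   centred on `dive_dur_mean`.
#' * surfacing: `surf_base` min, `surf_effort_coef` min per summed m/s^2,
#'   `surf_prca_coef` min per unit PrCA rate, `surf_noise_sd`,
#'   `surf_floor_s` (30), `extended_surf_prob` (0.013),
#'   `extended_surf_min` (3.5 min).
#' * drift dives: `drift_dive_prob` (0.10), `drift_noise_sd` (0.02 m/s),
#'   `drift_frac_min/max` (0.45/0.60 of dive time),
#'   `drift_min_depth` (70 m), `drift_start_max` (300 m; drift dives are
#'   rest dives at mid-water depths), `drift_effort_min/max`
#'   (0.5/2.5 m/s^3).
#' * condition template: `dr_init_mean/sd` (+0.15/0.04), `init_pos_frac`
#'   (0.85), `dr_init_neg_mean/sd` (-0.21/0.02), `dr_min_mean/sd`
#'   (-0.25/0.04), `dr_phase1_end` (50) and `dr_phase1_end_sd` (5),
#'   `switch_frac` (0.75 of survivors), `dr_switch_day_mean/sd` (93/15),
#'   `dr_peak_nonswitch_mean/sd`, `dr_phase2_end` (100) and SD,
#'   `dr_phase3_slope` (-0.0035 m/s per day).
#' * effort/foraging: `effort_neutral_min` (6 m/s^3),
#'   `effort_buoyancy_coef` (10 per |m/s|), `effort_sd` (0.5),
#'   `prca_juv_scale` (0.10), `prca_adult_scale` (0.05), `prca_sd` (0.04),
#'   `prca_decay_day` (100).
#' * morphometrics: `mass_mean/sd` (80/18, adults 267/60),
#'   `length_mean/sd` (139/11, adults 257/38).
#' * haul-outs: `haulout_pos_mean/sd` (8.7/4.4 d),
#'   `haulout_neg_mean/sd` (2.9/2.59 d).
#' * dive shape: `vr_min/max` (1.0/1.5 m/s transit rates),
#'   `wiggle_amp_max` (3 m), `min_bottom_s` (30).
#'
#' @return A named list of class `"generator_params"`.
#' @seealso [simulate_cohort()], [condition_model()]
#' @export
generator_params <- function(age_class = c("juvenile", "adult"),
                             seed = 1L, ...) {
  age_class <- match.arg(age_class)
  p <- if (age_class == "juvenile") .juvenile_defaults() else .adult_defaults()
  p$age_class <- age_class
  p$seed <- as.integer(seed)
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown generator parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  class(p) <- "generator_params"
  validate_params(p)
  p
}

.juvenile_defaults <- function() {
  list(
    n_individuals = 20L,
    trip_days_max = 338,
    dive_interval = 2,        # hours between recorded dives
    tag_death_frac = 0.40,
    tag_death_day_min = 15,
    tag_death_day_max = 100,
    tag_end_min = 150,
    # depth ontogeny (m)
    depth_mean_day0 = 60,  depth_sd_day0 = 15,
    depth_mean_day50 = 115, depth_sd_day50 = 21,
    depth_mean_month8 = 227, depth_sd_month8 = 50,
    month8_day = 240,
    adult_depth_mean = 474, adult_depth_sd = 79,
    depth_min = 25,
    # dive durations (min)
    dive_dur_mean = 12.5, dive_dur_sd = 5.0,
    dive_dur_ramp = 6.0, dive_dur_ramp_days = 180,
    dive_dur_min = 2.5,
    # surfacing model (min)
    surf_base = 0.76,
    surf_effort_coef = 2.1e-4,
    surf_prca_coef = 1.0,
    surf_noise_sd = 0.15,
    surf_floor_s = 30,
    extended_surf_prob = 0.013,
    extended_surf_min = 3.5,
    extended_surf_exp_mean = 2.0,
    # drift dives
    drift_dive_prob = 0.10,
    drift_noise_sd = 0.02,
    drift_frac_min = 0.45, drift_frac_max = 0.60,
    drift_min_depth = 70,
    drift_start_max = 300,
    drift_effort_min = 0.5, drift_effort_max = 2.5,
    # condition (drift-rate) template
    dr_init_mean = 0.15,  dr_init_sd = 0.04,
    init_pos_frac = 0.85,
    dr_init_neg_mean = -0.21, dr_init_neg_sd = 0.02,
    dr_min_mean = -0.25, dr_min_sd = 0.04,
    dr_phase1_end = 50, dr_phase1_end_sd = 5,
    switch_frac = 0.75,
    dr_switch_day_mean = 93, dr_switch_day_sd = 15,
    dr_peak_nonswitch_mean = -0.05, dr_peak_nonswitch_sd = 0.02,
    dr_phase2_end = 100, dr_phase2_end_sd = 10,
    dr_phase3_slope = -0.0035,
    # swimming effort / foraging
    effort_neutral_min = 6,
    effort_buoyancy_coef = 10,
    effort_sd = 0.5,
    prca_juv_scale = 0.10,
    prca_adult_scale = 0.05,
    prca_sd = 0.04,
    prca_decay_day = 100,
    # morphometrics
    mass_mean = 80,  mass_sd = 18,
    length_mean = 139, length_sd = 11,
    # haul-outs (days), keyed to buoyancy sign at return
    haulout_pos_mean = 8.7, haulout_pos_sd = 4.4,
    haulout_neg_mean = 2.9, haulout_neg_sd = 2.59,
    # dive shape
    vr_min = 1.0, vr_max = 1.5,
    wiggle_amp_max = 3,
    min_bottom_s = 30
  )
}

.adult_defaults <- function() {
  p <- .juvenile_defaults()
  p$n_individuals <- 9L
  p$trip_days_max <- 90
  p$dive_interval <- NA_real_   # continuous recording
  p$tag_death_frac <- 0
  p$tag_end_min <- 60
  p$depth_min <- 100
  p$dive_dur_mean <- 18.5
  p$dive_dur_ramp <- 0
  p$dive_dur_min <- 6
  # adults improve condition over the trip without becoming positive
  p$dr_init_mean <- -0.27
  p$dr_init_sd <- 0.03
  p$init_pos_frac <- 0
  p$dr_init_neg_mean <- -0.27
  p$dr_init_neg_sd <- 0.03
  p$dr_min_mean <- -0.27
  p$dr_min_sd <- 0.03
  p$dr_phase1_end <- 0
  p$dr_phase1_end_sd <- 0
  p$switch_frac <- 0
  p$dr_peak_nonswitch_mean <- -0.14
  p$dr_peak_nonswitch_sd <- 0.03
  p$dr_phase2_end <- 90
  p$dr_phase2_end_sd <- 5
  p$dr_phase3_slope <- 0
  p$prca_juv_scale <- p$prca_adult_scale
  p$mass_mean <- 267
  p$mass_sd <- 60
  p$length_mean <- 257
  p$length_sd <- 38
  p
}

validate_params <- function(p) {
  stopifnot(p$n_individuals >= 1)
  probs <- c(p$tag_death_frac, p$extended_surf_prob, p$drift_dive_prob,
             p$init_pos_frac, p$switch_frac)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  sds <- c(p$depth_sd_day0, p$depth_sd_day50, p$depth_sd_month8,
           p$adult_depth_sd, p$dive_dur_sd, p$surf_noise_sd,
           p$drift_noise_sd, p$dr_init_sd, p$dr_min_sd, p$dr_switch_day_sd,
           p$effort_sd, p$prca_sd, p$mass_sd, p$length_sd)
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  if (!is.na(p$dive_interval) && p$dive_interval <= 0)
    stop("dive_interval must be > 0 (or NA for continuous recording)")
  invisible(p)
}

#' @export
print.generator_params <- function(x, ...) {
  cat("<generator_params> age_class =", x$age_class,
      " n =", x$n_individuals,
      " seed =", x$seed, "\n")
  cat("  dive interval:",
      if (is.na(x$dive_interval)) "continuous" else paste(x$dive_interval, "h"),
      " trip_days_max:", x$trip_days_max, "\n")
  invisible(x)
}

# Deterministic per-individual sub-seed from the master seed, so cohort
# size changes never reshuffle earlier individuals.
individual_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 104729 + 7919 * as.numeric(i)) %% 2147483629)
}
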