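#' Three-phase body-condition (drift-rate) template
#'
#' True drift rate, in m/s (upward positive), of one individual on a given
#' day of its trip. The trajectory is continuous piecewise-linear with three
#' phases: a departure decline from the initial drift rate to a trough at
#' the end of phase 1, a central-phase recovery towards a peak at the end of
#' phase 2 (crossing zero -- the buoyancy switch -- only for individuals
#' whose peak is positive), and a final return-phase decline. Individuals
#' that never become positively buoyant simply have a negative phase-2 peak.
#'
#' @param day numeric vector of days since departure (>= 0).
#' @param params a [generator_params()] object (used for the physical
#'   drift-rate band within which the trajectory is clamped).
#' @param offsets per-individual template, a list with elements
#'   `dr_init`, `dr_min`, `dr_peak` (m/s), `phase1_end`, `phase2_end`
#'   (days) and `phase3_slope` (m/s per day). See
#'   [draw_condition_offsets()].
#' @return numeric vector of true drift rates, same length as `day`.
#' @export
condition_model <- function(day, params, offsets) {
  stopifnot(all(day >= 0))
  o <- offsets
  p1 <- o$phase1_end
  p2 <- o$phase2_end
  stopifnot(p2 > p1)
  dr <- numeric(length(day))
  ph1 <- day <= p1
  ph2 <- day > p1 & day <= p2
  ph3 <- day > p2
  if (p1 > 0) {
    dr[ph1] <- o$dr_init + (o$dr_min - o$dr_init) * day[ph1] / p1
  } else {
    dr[ph1] <- o$dr_min
  }
  dr[ph2] <- o$dr_min + (o$dr_peak - o$dr_min) * (day[ph2] - p1) / (p2 - p1)
  # return-phase decline levels off just above the departure trough: the
  # animal returns towards lean condition but does not keep sinking faster
  # than it ever did on departure
  floor3 <- min(o$dr_peak, o$dr_min + 0.06)
  dr[ph3] <- pmax(o$dr_peak + o$phase3_slope * (day[ph3] - p2), floor3)
  # keep the truth inside the physically admissible drift band
  pmin(pmax(dr, -0.295), 0.595)
}

#' Draw one individual's condition-template offsets
#'
#' Samples the per-individual parameters of the three-phase drift-rate
#' template. The buoyancy-switch day of switching individuals is drawn
#' directly (normal around `dr_switch_day_mean`), and the phase-2 end is
#' derived from it by linearity, so the day of the zero crossing is an
#' input of the generator rather than an emergent quantity.
#'
#' @param params a [generator_params()] object.
#' @param positive_init logical; initially positively buoyant?
#' @param switcher logical; does this individual reach positive buoyancy
#'   during the central phase?
#' @return list with `dr_init`, `dr_min`, `dr_peak`, `phase1_end`,
#'   `phase2_end`, `phase3_slope`, `switch_day` (NA for non-switchers).
#'   Random draws use the current RNG state.
#' @export
draw_condition_offsets <- function(params, positive_init = TRUE,
                                   switcher = FALSE) {
  p <- params
  dr_init <- if (positive_init) {
    stats::rnorm(1, p$dr_init_mean, p$dr_init_sd)
  } else {
    stats::rnorm(1, p$dr_init_neg_mean, p$dr_init_neg_sd)
  }
  p1 <- max(0, stats::rnorm(1, p$dr_phase1_end, p$dr_phase1_end_sd))
  if (p1 > 0) {
    dr_min <- min(stats::rnorm(1, p$dr_min_mean, p$dr_min_sd), -0.05)
    dr_min <- min(dr_min, dr_init - 0.01)  # phase 1 always declines
  } else {
    dr_min <- dr_init  # no departure decline (adult template)
  }
  if (switcher) {
    s <- stats::rnorm(1, p$dr_switch_day_mean, p$dr_switch_day_sd)
    s <- min(s, p$trip_days_max - 30)
    s <- max(s, p1 + 10)   # the switch always follows the departure trough
    dr_peak <- stats::runif(1, 0.03, 0.09)
    # zero crossing of the rising limb at day s:
    # s = p1 + (p2 - p1) * (0 - dr_min) / (dr_peak - dr_min)
    p2 <- p1 + (s - p1) * (dr_peak - dr_min) / (0 - dr_min)
    switch_day <- s
  } else {
    dr_peak <- min(stats::rnorm(1, p$dr_peak_nonswitch_mean,
                                p$dr_peak_nonswitch_sd), -0.005)
    dr_peak <- max(dr_peak, dr_min + 0.005)
    p2 <- max(p1 + 5, stats::rnorm(1, p$dr_phase2_end, p$dr_phase2_end_sd))
    switch_day <- NA_real_
  }
  list(dr_init = dr_init, dr_min = dr_min, dr_peak = dr_peak,
       phase1_end = p1, phase2_end = p2,
       phase3_slope = p$dr_phase3_slope, switch_day = switch_day)
}
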