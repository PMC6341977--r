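# Trip-phase delineation from the drift-rate trajectory, departure-phase
# slopes, and the body-mass-index residual.

#' Delineate the three trip phases from a condition series
#'
#' Works on the smoothed daily drift-rate trajectory. The departure phase
#' ends at the global minimum of the smoothed series (`phase1_end`); the
#' central phase ends at the subsequent maximum (`phase2_end`), reported
#' only when a decline of at least `decline_min` m/s is observed after it
#' (otherwise no return phase is declared); the buoyancy switch
#' (`switch_day`) is the first day after `phase1_end` on which the
#' smoothed drift rate is positive. A monotonically decreasing series
#' yields a single departure phase (`phase1_end` = last day, others
#' missing).
#'
#' @param series a `condition_series` from [daily_drift_series()], with at
#'   least `min_days` days carrying a smoothed value.
#' @param decline_min decline (m/s) after the candidate phase-2 maximum
#'   required to declare a return phase; guards against noise-driven
#'   phantom return phases.
#' @param min_days minimum days with data; shorter series return all-NA
#'   phases with a message.
#' @return one-row data.frame (`trip_phases`): `phase1_end`, `phase2_end`,
#'   `switch_day` (days; NA where undetected), `n_days` with data.
#' @export
segment_phases <- function(series, decline_min = 0.02, min_days = 30L) {
  ok <- !is.na(series$dr_smooth)
  n_days <- sum(ok)
  out <- data.frame(phase1_end = NA_real_, phase2_end = NA_real_,
                    switch_day = NA_real_, n_days = n_days)
  if (!is.null(attr(series, "individual_id")))
    out <- cbind(individual_id = attr(series, "individual_id"), out)
  class(out) <- c("trip_phases", "data.frame")
  if (n_days < min_days) {
    message("condition series has ", n_days, " days with data (< ",
            min_days, "); phases not delineated")
    return(out)
  }
  day <- series$day[ok]
  dr <- series$dr_smooth[ok]
  i1 <- which.min(dr)
  out$phase1_end <- day[i1]
  after <- seq(i1, length(dr))
  if (length(after) > 1L) {
    i2 <- after[which.max(dr[after])]
    tail_min <- if (i2 < length(dr)) min(dr[seq(i2, length(dr))]) else dr[i2]
    if (i2 > i1 && dr[i2] - tail_min >= decline_min)
      out$phase2_end <- day[i2]
    pos <- after[-1][dr[after[-1]] > 0]
    if (length(pos)) out$switch_day <- day[pos[1]]
  }
  out
}

#' Departure-phase linear rate of change
#'
#' Ordinary least-squares line through one individual's daily values of a
#' variable (drift rate or dive duration) over the departure phase
#' (days 0 .. `phase1_end`).
#'
#' @param values data.frame with columns `day` and `value` (daily values;
#'   missing allowed).
#' @param phases a `trip_phases` row from [segment_phases()].
#' @param variable label stored in the output (`"drift_rate"` or
#'   `"dive_duration"`).
#' @param min_days minimum days with data inside the window.
#' @return one-row data.frame: `variable`, `intercept`, `slope`,
#'   `se_intercept`, `se_slope`, `n_days`, `window` -- or `NULL` (with a
#'   message) when there is not enough data.
#' @export
departure_slope <- function(values, phases,
                            variable = c("drift_rate", "dive_duration"),
                            min_days = 10L) {
  variable <- match.arg(variable)
  p1 <- phases$phase1_end
  if (is.na(p1)) {
    message("no departure phase available; slope not fitted")
    return(NULL)
  }
  v <- values[!is.na(values$value) & values$day <= p1, , drop = FALSE]
  if (nrow(v) < min_days) {
    message("only ", nrow(v), " days with data in [0, ", p1,
            "]; slope not fitted")
    return(NULL)
  }
  fit <- stats::lm(value ~ day, data = v)
  cf <- summary(fit)$coefficients
  out <- data.frame(variable = variable,
                    intercept = cf[1, 1], slope = cf[2, 1],
                    se_intercept = cf[1, 2], se_slope = cf[2, 2],
                    n_days = nrow(v), window = p1)
  if ("individual_id" %in% names(phases))
    out <- cbind(individual_id = phases$individual_id, out)
  out
}

#' Body mass index as mass-on-length regression residuals
#'
#' Cohort BMI: residuals of an OLS regression of body mass at departure on
#' length, so that the index is independent of body length. Residuals sum
#' to zero and are orthogonal to length by construction.
#'
#' @param morph data.frame with columns `individual_id`, `mass_kg`,
#'   `length_cm` (>= 3 individuals, positive values).
#' @return data.frame: `individual_id`, `mass_kg`, `length_cm`, `bmi_kg`.
#' @export
compute_bmi <- function(morph) {
  stopifnot(nrow(morph) >= 3, all(morph$mass_kg > 0),
            all(morph$length_cm > 0))
  if (stats::var(morph$length_cm) == 0) {
    warning("zero length variance; BMI falls back to mass - cohort mean mass")
    bmi <- morph$mass_kg - mean(morph$mass_kg)
  } else {
    bmi <- stats::residuals(stats::lm(mass_kg ~ length_cm, data = morph))
  }
  data.frame(individual_id = morph$individual_id,
             mass_kg = morph$mass_kg, length_cm = morph$length_cm,
             bmi_kg = as.numeric(bmi))
}
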