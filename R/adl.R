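# Aerobic-dive-limit analyses: phase-wise theoretical-ADL exceedance,
# behavioural-ADL breakpoint on the surface-vs-dive-duration relation,
# extended-surface flagging, and surface-duration relations.

#' Theoretical aerobic-dive-limit thresholds
#'
#' Fixed dive-duration thresholds (min) per juvenile trip phase, plus the
#' adult threshold. Juvenile thresholds must increase across phases,
#' tracking the growth of oxygen stores over the first year.
#'
#' @param departure,central,return juvenile thresholds (min).
#' @param adult adult-female threshold (min).
#' @return named list of thresholds.
#' @export
tadl_thresholds <- function(departure = 6, central = 10, return_ = 18,
                            adult = 28) {
  if (!(departure < central && central < return_))
    stop("juvenile tADL thresholds must be strictly increasing across phases")
  list(departure = departure, central = central, return = return_,
       adult = adult)
}

# Assign each dive to a trip phase from its individual's phase boundaries.
.assign_phase <- function(dives, phases) {
  i <- match(dives$individual_id, phases$individual_id)
  p1 <- phases$phase1_end[i]
  p2 <- phases$phase2_end[i]
  ph <- rep(NA_character_, nrow(dives))
  ph[!is.na(p1) & dives$day <= p1] <- "departure"
  mid <- !is.na(p1) & dives$day > p1
  ph[mid & (is.na(p2) | dives$day <= p2)] <- "central"
  ph[mid & !is.na(p2) & dives$day > p2] <- "return"
  ph
}

#' Proportion of dives exceeding the theoretical ADL, per phase
#'
#' For each individual and trip phase, the proportion of dives whose
#' duration exceeds that phase's tADL threshold; pooled as mean +/- SD
#' across individuals. Adults (no trip phases) are assessed against the
#' single adult threshold.
#'
#' @param dives stacked abstracted dives (needs `individual_id`, `day`,
#'   `duration_s`).
#' @param phases stacked `trip_phases` rows, one per individual; ignored
#'   for `age_class = "adult"`.
#' @param thresholds from [tadl_thresholds()].
#' @param age_class `"juvenile"` or `"adult"`.
#' @return list with `by_individual` (individual x phase proportions) and
#'   `pooled` (per phase: mean, sd, n individuals). Phases with no dives
#'   are reported missing.
#' @export
tadl_exceedance <- function(dives, phases = NULL,
                            thresholds = tadl_thresholds(),
                            age_class = c("juvenile", "adult")) {
  age_class <- match.arg(age_class)
  dur_min <- dives$duration_s / 60
  if (age_class == "adult") {
    ph <- rep("adult", nrow(dives))
  } else {
    stopifnot(!is.null(phases))
    ph <- .assign_phase(dives, phases)
  }
  thr <- unlist(thresholds)[ph]
  ok <- !is.na(ph)
  if (!any(ok)) {
    empty <- data.frame(individual_id = character(0), phase = character(0),
                        n_dives = integer(0), proportion = numeric(0))
    return(list(by_individual = empty,
                pooled = data.frame(phase = character(0), mean = numeric(0),
                                    sd = numeric(0),
                                    n_individuals = integer(0))))
  }
  exceed <- dur_min > thr
  agg <- stats::aggregate(
    exceed[ok],
    by = list(individual_id = dives$individual_id[ok], phase = ph[ok]),
    FUN = function(z) c(prop = mean(z), n = length(z)))
  by_ind <- data.frame(individual_id = agg$individual_id, phase = agg$phase,
                       n_dives = agg$x[, "n"], proportion = agg$x[, "prop"])
  pooled <- do.call(rbind, lapply(split(by_ind, by_ind$phase), function(d)
    data.frame(phase = d$phase[1], mean = mean(d$proportion),
               sd = stats::sd(d$proportion), n_individuals = nrow(d))))
  rownames(pooled) <- NULL
  list(by_individual = by_ind, pooled = pooled)
}

#' Flag extended post-dive surface durations
#'
#' @param dives stacked dives with `surface_s`.
#' @param cutoff_min extended-surface cutoff (min, default 3.5).
#' @return list with `fraction` (pooled fraction of dives flagged) and
#'   `flags` (logical per dive). Flagged dives are excluded from the
#'   breakpoint and surface-relation fits.
#' @export
flag_extended_surfaces <- function(dives, cutoff_min = 3.5) {
  flags <- dives$surface_s / 60 > cutoff_min
  list(fraction = mean(flags), flags = flags)
}

#' Behavioural-ADL breakpoint on the surface-vs-dive-duration relation
#'
#' Bins dive durations into 1-min bins, takes the median surface duration
#' and median dive duration per bin, and fits every continuous two-segment
#' piecewise-linear model (median surface vs median duration) with the
#' breakpoint at an interior bin edge, selecting the minimum sum of
#' squared errors. No breakpoint (no detectable behavioural ADL) is
#' reported when the best two-segment fit reduces the SSE by less than
#' `min_sse_gain` relative to a single line, or when the upper slope does
#' not exceed the lower slope. Extended surface durations are excluded
#' first.
#'
#' @param dives stacked dives (`duration_s`, `surface_s`); at least
#'   `min_dives` after exclusion.
#' @param extended_cutoff_min passed to [flag_extended_surfaces()].
#' @param min_sse_gain minimum relative SSE reduction (default 0.10).
#' @param min_dives,min_bins minimum data requirements.
#' @param min_per_bin duration bins holding fewer dives than this are
#'   dropped before the fit; tail bins with a handful of dives otherwise
#'   contribute unstable medians.
#' @return list (`badl_fit`): `breakpoint` (min, NA when none),
#'   `slope_below`, `slope_above` (min surface per min dive), `sse`,
#'   `sse_line`, `n_bins`, `diagnostic`.
#' @export
fit_badl_breakpoint <- function(dives, extended_cutoff_min = 3.5,
                                min_sse_gain = 0.10, min_dives = 100L,
                                min_bins = 6L, min_per_bin = 20L) {
  keep <- !flag_extended_surfaces(dives, extended_cutoff_min)$flags
  d <- dives$duration_s[keep] / 60
  s <- dives$surface_s[keep] / 60
  if (length(d) < min_dives)
    stop("breakpoint fit needs at least ", min_dives, " dives")
  bin <- floor(d)
  med <- tapply(s, bin, stats::median)
  mdur <- tapply(d, bin, stats::median)
  cnt <- tapply(s, bin, length)
  x <- as.numeric(mdur[cnt >= min_per_bin])  # per-bin median duration
  y <- as.numeric(med[cnt >= min_per_bin])
  out <- list(breakpoint = NA_real_, slope_below = NA_real_,
              slope_above = NA_real_, sse = NA_real_, sse_line = NA_real_,
              n_bins = length(x), diagnostic = "ok")
  class(out) <- "badl_fit"
  if (length(x) < min_bins) {
    out$diagnostic <- sprintf("only %d duration bins (< %d)", length(x),
                              min_bins)
    return(out)
  }
  line_fit <- stats::lm(y ~ x)
  sse_line <- sum(stats::residuals(line_fit)^2)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0 || sse_line <= 1e-10 * tss) {
    out$sse <- out$sse_line <- sse_line
    out$slope_below <- out$slope_above <- unname(stats::coef(line_fit)[2])
    out$diagnostic <- "no detectable behavioural ADL (single line fits exactly)"
    return(out)
  }
  kmin <- min(floor(x)); kmax <- max(floor(x))
  cands <- if (kmax - 1L >= kmin + 2L) seq(kmin + 2L, kmax - 1L)
           else integer(0)             # >= 2 bins on each side
  if (!length(cands)) {
    out$diagnostic <- "no interior bin edges available"
    return(out)
  }
  best <- list(sse = Inf, bp = NA_real_, b1 = NA_real_, b2 = NA_real_)
  for (bp in cands) {
    h <- pmax(x - bp, 0)
    fit <- stats::lm(y ~ x + h)
    sse <- sum(stats::residuals(fit)^2)
    if (sse < best$sse) {
      cf <- stats::coef(fit)
      best <- list(sse = sse, bp = bp, b1 = unname(cf["x"]),
                   b2 = unname(cf["x"] + cf["h"]))
    }
  }
  out$sse <- best$sse
  out$sse_line <- sse_line
  out$slope_below <- best$b1
  out$slope_above <- best$b2
  gain <- 1 - best$sse / sse_line
  if (!is.finite(gain) || gain < min_sse_gain) {
    out$diagnostic <- "no detectable behavioural ADL (SSE gain below cutoff)"
  } else if (best$b2 <= best$b1) {
    out$diagnostic <- "no detectable behavioural ADL (no upward inflection)"
  } else {
    out$breakpoint <- best$bp
  }
  out
}

#' @export
print.badl_fit <- function(x, ...) {
  if (is.na(x$breakpoint)) {
    cat("bADL: none detected --", x$diagnostic, "\n")
  } else {
    cat(sprintf("bADL breakpoint at %.1f min (slopes %.3f -> %.3f)\n",
                x$breakpoint, x$slope_below, x$slope_above))
  }
  invisible(x)
}

#' Surface-duration relations to dive duration, effort and PrCA rate
#'
#' Binned-median OLS slope of post-dive surface duration (min) against
#' each predictor, per age class, with seeded bootstrap confidence
#' intervals (resampling dives). Extended surfaces are excluded.
#'
#' @param metrics stacked dive metrics (from the pipeline): needs
#'   `surface_s`, `duration_s`, `total_effort`, `bottom_prca_rate` and
#'   `age_class` columns.
#' @param predictors subset of `c("dive_duration", "total_effort",
#'   "bottom_prca_rate")`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param n_bins bins for non-duration predictors (duration uses 1-min
#'   bins).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame: `age_class`, `predictor`, `slope`, `ci_lo`,
#'   `ci_hi`, `n_dives`. Slopes are NA for degenerate predictors.
#' @export
surface_relations <- function(metrics,
                              predictors = c("dive_duration", "total_effort",
                                             "bottom_prca_rate"),
                              n_boot = 1000L, n_bins = 20L, seed = 1L) {
  keep <- !flag_extended_surfaces(metrics)$flags
  m <- metrics[keep, , drop = FALSE]
  set.seed(seed)
  rows <- list()
  for (ac in unique(m$age_class)) {
    ma <- m[m$age_class == ac, , drop = FALSE]
    s <- ma$surface_s / 60
    for (pr in predictors) {
      xall <- switch(pr,
                     dive_duration = ma$duration_s / 60,
                     total_effort = ma$total_effort,
                     bottom_prca_rate = ma$bottom_prca_rate)
      ok <- !is.na(xall)
      x <- xall[ok]; y <- s[ok]
      if (length(x) < 20 || stats::var(x) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          age_class = ac, predictor = pr, slope = NA_real_,
          ci_lo = NA_real_, ci_hi = NA_real_, n_dives = length(x))
        next
      }
      slope_fun <- function(idx) {
        xi <- x[idx]; yi <- y[idx]
        b <- if (pr == "dive_duration") floor(xi)
             else findInterval(xi, stats::quantile(xi, seq(0, 1, length.out =
                n_bins + 1L)), rightmost.closed = TRUE, all.inside = TRUE)
        my <- tapply(yi, b, stats::median)
        mx <- tapply(xi, b, stats::median)
        if (length(my) < 3 || stats::var(mx) == 0) return(NA_real_)
        unname(stats::coef(stats::lm(as.numeric(my) ~ as.numeric(mx)))[2])
      }
      est <- slope_fun(seq_along(x))
      bs <- vapply(seq_len(n_boot), function(i)
        slope_fun(sample.int(length(x), replace = TRUE)), numeric(1))
      ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        age_class = ac, predictor = pr, slope = est,
        ci_lo = unname(ci[1]), ci_hi = unname(ci[2]), n_dives = length(x))
    }
  }
  do.call(rbind, rows)
}
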