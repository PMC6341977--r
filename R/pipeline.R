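# End-to-end orchestration: simulate -> abstract -> drift filter ->
# condition trajectory -> ADL, with a structured report of every cohort
# statistic, and the command-line dispatcher.

.stat3 <- function(x) {
  x <- x[!is.na(x)]
  list(mean = if (length(x)) mean(x) else NA_real_,
       sd = if (length(x) > 1) stats::sd(x) else NA_real_,
       n = length(x))
}

# Daily means of a per-dive variable for one individual.
.daily_values <- function(days, values) {
  d <- floor(days)
  m <- tapply(values, d, mean)
  data.frame(day = as.numeric(names(m)), value = as.numeric(m))
}

# Analyse one simulated cohort that has already been reduced to stacked
# dives/segments tables plus per-individual truth.
.analyse_cohort <- function(ac, dives, segments, morph, truths, config) {
  ct <- do.call(drift_filter_control, config$filter)
  est <- drift_estimates(dives, segments, ct)
  ids <- unique(dives$individual_id)

  series <- phase_rows <- slope_rows <- list()
  early_dr <- switch_days <- rep(NA_real_, length(ids))
  names(early_dr) <- names(switch_days) <- ids
  for (id in ids) {
    ei <- est[est$individual_id == id, , drop = FALSE]
    end_day <- max(dives$day[dives$individual_id == id])
    s <- daily_drift_series(ei, window = config$smoothing$window,
                            min_obs = config$smoothing$min_obs,
                            end_day = end_day)
    attr(s, "individual_id") <- id
    series[[id]] <- s
    ph <- if (identical(config$phases$mode, "fixed")) {
      out <- data.frame(individual_id = id, phase1_end = 50,
                        phase2_end = 100, switch_day = NA_real_,
                        n_days = sum(!is.na(s$dr_smooth)))
      pos <- which(s$day > 50 & !is.na(s$dr_smooth) & s$dr_smooth > 0)
      if (length(pos)) out$switch_day <- s$day[pos[1]]
      out
    } else {
      suppressMessages(segment_phases(s,
                                      decline_min = config$phases$decline_min,
                                      min_days = config$phases$min_days))
    }
    phase_rows[[id]] <- ph
    switch_days[id] <- ph$switch_day
    # initial drift rate of individuals starting positively buoyant
    sm <- s$dr_smooth[!is.na(s$dr_smooth)]
    if (length(sm) && sm[1] > 0 && any(ei$day <= 5))
      early_dr[id] <- mean(ei$drift_rate[ei$day <= 5])
    dr_slope <- suppressMessages(departure_slope(
      data.frame(day = s$day, value = s$dr_raw), ph, "drift_rate"))
    di <- dives[dives$individual_id == id, , drop = FALSE]
    dur_slope <- suppressMessages(departure_slope(
      .daily_values(di$day, di$duration_s / 60), ph, "dive_duration"))
    slope_rows[[id]] <- rbind(dr_slope, dur_slope)
  }
  phases <- do.call(rbind, phase_rows)
  rownames(phases) <- NULL
  slopes <- do.call(rbind, slope_rows)
  if (!is.null(slopes)) rownames(slopes) <- NULL

  bmi <- compute_bmi(morph)
  metrics <- .metrics_table(dives, segments)
  metrics$age_class <- ac
  thr <- do.call(tadl_thresholds, stats::setNames(
    config$tadl, sub("^return$", "return_", names(config$tadl))))
  tadl <- tadl_exceedance(dives, phases, thr, age_class = ac)
  ext <- flag_extended_surfaces(dives,
                                cutoff_min = config$adl$extended_cutoff_min)
  badl <- fit_badl_breakpoint(dives,
                              extended_cutoff_min =
                                config$adl$extended_cutoff_min)
  rel <- surface_relations(metrics, n_boot = config$adl$n_boot,
                           seed = config$seed)

  per_ind_surface <- tapply(dives$surface_s / 60, dives$individual_id, mean)
  in50 <- dives$day >= 47 & dives$day <= 53
  in8 <- dives$day >= 225 & dives$day <= 255

  # correlation between initial drift rate and its departure-phase slope
  cor_init_slope <- NA_real_
  if (!is.null(slopes)) {
    sl <- slopes[slopes$variable == "drift_rate", , drop = FALSE]
    iv <- early_dr[sl$individual_id]
    ok <- !is.na(iv)
    if (sum(ok) >= 3)
      cor_init_slope <- stats::cor(iv[ok], sl$slope[ok])
  }

  list(
    age_class = ac,
    n_individuals = length(ids),
    n_dives = nrow(dives),
    n_drift_estimates = nrow(est),
    filter_drops = as.list(attr(est, "drops")),
    dive_duration_min = .stat3(dives$duration_s / 60),
    surface_min_by_individual = .stat3(as.numeric(per_ind_surface)),
    surface_min_pooled = .stat3(dives$surface_s / 60),
    max_depth_m = .stat3(dives$max_depth_m),
    depth_day50_m = .stat3(dives$max_depth_m[in50]),
    depth_month8_m = .stat3(dives$max_depth_m[in8]),
    switch_day = .stat3(switch_days),
    initial_drift_rate = .stat3(early_dr),
    cor_initial_dr_slope = cor_init_slope,
    tadl = tadl,
    extended_surface_fraction = ext$fraction,
    badl = badl,
    surface_relations = rel,
    phases = phases, slopes = slopes, bmi = bmi,
    drift = est, series = series, metrics = metrics
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> abstract -> drift filter -> condition trajectory ->
#' ADL for every cohort in the configuration and assembles a structured
#' report of the cohort statistics (each with mean, SD, n). Individuals
#' are processed one at a time so 1-Hz profiles never accumulate in
#' memory.
#'
#' @param config a `divekit_config` from [default_config()] or
#'   [read_config()].
#' @param out_dir optional output directory; when given, the abstracted
#'   dives, drift estimates, phases, slopes, BMI, ADL tables and the
#'   report (JSON + text) are written beneath it, one subdirectory per
#'   cohort.
#' @param level `"profile"` (default; full 1-Hz synthesis and broken-stick
#'   abstraction) or `"segment"` (fast summary-level path).
#' @param cohorts optional subset of the configured cohorts to run.
#' @return a `divekit_report` list (one element per cohort plus the
#'   configuration echo).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         level = c("profile", "segment"), cohorts = NULL) {
  level <- match.arg(level)
  run <- names(config$cohorts)
  if (!is.null(cohorts)) run <- intersect(run, cohorts)
  report <- list(seed = config$seed, cohorts = list())
  for (ac in run) {
    p <- config$cohorts[[ac]]
    class(p) <- "generator_params"
    validate_params(p)
    groups <- .cohort_groups(p)
    dv_parts <- seg_parts <- morph_parts <- vector("list", p$n_individuals)
    truths <- vector("list", p$n_individuals)
    for (i in seq_len(p$n_individuals)) {
      rec <- simulate_individual(p, i, group = groups[[i]], level = level)
      summ <- .record_summaries(rec)
      dv_parts[[i]] <- summ$dives
      seg_parts[[i]] <- summ$segments
      morph_parts[[i]] <- rec$morph
      truths[[i]] <- rec$truth
      names(truths)[i] <- rec$individual_id
    }
    dives <- do.call(rbind, c(dv_parts, make.row.names = FALSE))
    segments <- do.call(rbind, c(seg_parts, make.row.names = FALSE))
    morph <- do.call(rbind, c(morph_parts, make.row.names = FALSE))
    res <- .analyse_cohort(ac, dives, segments, morph, truths, config)
    res$truths <- truths
    report$cohorts[[ac]] <- res
    if (!is.null(out_dir)) {
      d <- file.path(out_dir, ac)
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
      write_abstracted_csv(list(dives = dives, segments = segments),
                           file.path(d, "dives_abstracted.csv"))
      .fwrite(res$drift, file.path(d, "drift.csv"))
      .fwrite(res$phases, file.path(d, "phases.csv"))
      if (!is.null(res$slopes)) .fwrite(res$slopes,
                                        file.path(d, "slopes.csv"))
      .fwrite(res$bmi, file.path(d, "bmi.csv"))
      .fwrite(res$tadl$by_individual, file.path(d, "tadl.csv"))
      jsonlite::write_json(res$badl[c("breakpoint", "slope_below",
                                      "slope_above", "sse", "sse_line",
                                      "n_bins", "diagnostic")],
                           file.path(d, "badl.json"), auto_unbox = TRUE,
                           digits = NA, na = "null")
      .fwrite(res$surface_relations,
              file.path(d, "surface_relations.csv"))
    }
  }
  class(report) <- "divekit_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_summary(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(report_text(report), file.path(out_dir, "report.txt"))
  }
  report
}

#' Machine-readable summary of a pipeline report
#'
#' Flattens a `divekit_report` to plain lists of the named cohort
#' statistics (mean/sd/n), suitable for JSON serialisation.
#' @param report a `divekit_report`.
#' @return nested list.
#' @export
report_summary <- function(report) {
  list(seed = report$seed, cohorts = lapply(report$cohorts, function(co) {
    list(age_class = co$age_class, n_individuals = co$n_individuals,
         n_dives = co$n_dives, n_drift_estimates = co$n_drift_estimates,
         filter_drops = co$filter_drops,
         dive_duration_min = co$dive_duration_min,
         surface_min_by_individual = co$surface_min_by_individual,
         surface_min_pooled = co$surface_min_pooled,
         max_depth_m = co$max_depth_m,
         depth_day50_m = co$depth_day50_m,
         depth_month8_m = co$depth_month8_m,
         switch_day = co$switch_day,
         initial_drift_rate = co$initial_drift_rate,
         cor_initial_dr_slope = co$cor_initial_dr_slope,
         tadl = co$tadl$pooled,
         extended_surface_fraction = co$extended_surface_fraction,
         badl = co$badl[c("breakpoint", "slope_below", "slope_above",
                          "diagnostic")],
         surface_relations = co$surface_relations)
  }))
}

#' @rdname report_summary
#' @return for `report_text()`, a character vector of human-readable lines.
#' @export
report_text <- function(report) {
  fmt <- function(s, digits = 2)
    sprintf("%.*f +/- %.*f (n=%d)", digits, s$mean, digits,
            if (is.na(s$sd)) 0 else s$sd, s$n)
  out <- c(sprintf("divekit pipeline report (seed %d)", report$seed))
  for (co in report$cohorts) {
    out <- c(out, "",
      sprintf("== %s cohort: %d individuals, %d dives, %d drift estimates",
              co$age_class, co$n_individuals, co$n_dives,
              co$n_drift_estimates),
      sprintf("  dive duration (min):        %s", fmt(co$dive_duration_min, 1)),
      sprintf("  surface, per-ind mean (min): %s",
              fmt(co$surface_min_by_individual)),
      sprintf("  max depth (m):              %s", fmt(co$max_depth_m, 0)))
    if (co$age_class == "juvenile") {
      out <- c(out,
        sprintf("  depth, day 50 window (m):   %s", fmt(co$depth_day50_m, 0)),
        sprintf("  depth, month 8 window (m):  %s", fmt(co$depth_month8_m, 0)),
        sprintf("  buoyancy switch day:        %s", fmt(co$switch_day, 1)),
        sprintf("  initial drift rate (m/s):   %s",
                fmt(co$initial_drift_rate, 3)),
        sprintf("  cor(initial DR, slope):     %.2f",
                co$cor_initial_dr_slope))
    }
    pooled <- co$tadl$pooled
    ord <- match(c("departure", "central", "return", "adult"), pooled$phase)
    pooled <- pooled[ord[!is.na(ord)], , drop = FALSE]
    for (k in seq_len(nrow(pooled))) {
      r <- pooled[k, ]
      out <- c(out, sprintf("  tADL exceedance, %-9s   %.0f%% +/- %.0f%%",
                            paste0(r$phase, ":"), 100 * r$mean,
                            100 * ifelse(is.na(r$sd), 0, r$sd)))
    }
    out <- c(out,
      sprintf("  extended surfaces (>3.5 min): %.1f%%",
              100 * co$extended_surface_fraction),
      sprintf("  bADL: %s",
              if (is.na(co$badl$breakpoint)) co$badl$diagnostic
              else sprintf("breakpoint %.1f min", co$badl$breakpoint)))
  }
  out
}

#' @export
print.divekit_report <- function(x, ...) {
  writeLines(report_text(x))
  invisible(x)
}

# --- command-line dispatcher ---------------------------------------------

.cli_arg <- function(args, name, default = NULL) {
  i <- which(args == name)
  if (length(i)) args[i[1] + 1L] else default
}

#' Command-line entry point
#'
#' Dispatcher behind the `divekit` command-line script:
#' `divekit simulate|abstract|drift|condition|adl|report|all` with global
#' options `--config <yaml>`, `--seed <int>`, `--out <path>`, plus
#' stage-specific `--in`, `--drift`, `--morph`, `--phases`, `--level`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status: 0 ok, 2 schema error, 3 config error.
#' @export
divekit_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: divekit <simulate|abstract|drift|condition|adl|report|all>",
            " [--config f] [--seed n] [--out d] [--in f] ...")
    return(3L)
  }
  cmd <- args[1]
  status <- tryCatch({
    seed <- as.integer(.cli_arg(args, "--seed", "1"))
    cfg_path <- .cli_arg(args, "--config")
    cfg <- if (is.null(cfg_path)) default_config(seed = seed)
           else read_config(cfg_path)
    cfg$seed <- seed
    for (ac in names(cfg$cohorts)) cfg$cohorts[[ac]]$seed <- seed
    out <- .cli_arg(args, "--out", ".")
    level <- .cli_arg(args, "--level", "profile")
    switch(cmd,
      simulate = {
        for (ac in names(cfg$cohorts)) {
          p <- cfg$cohorts[[ac]]; class(p) <- "generator_params"
          write_cohort_csv(simulate_cohort(p, level = level),
                           file.path(out, ac))
        }
      },
      abstract = {
        cohort <- read_cohort_csv(.cli_arg(args, "--in", "."))
        write_abstracted_csv(abstract_cohort(cohort),
                             file.path(out, "dives_abstracted.csv"))
      },
      drift = {
        ab <- read_abstracted_csv(.cli_arg(args, "--in",
                                           "dives_abstracted.csv"))
        est <- drift_estimates(ab$dives, ab$segments,
                               do.call(drift_filter_control, cfg$filter))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        .fwrite(est, file.path(out, "drift.csv"))
      },
      condition = {
        est <- .fread(.cli_arg(args, "--drift", "drift.csv"))
        morph <- .fread(.cli_arg(args, "--morph", "morphometrics.csv"))
        names(morph)[names(morph) == "id"] <- "individual_id"
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        rows <- slr <- list()
        for (id in unique(est$individual_id)) {
          s <- daily_drift_series(est[est$individual_id == id, ],
                                  window = cfg$smoothing$window,
                                  min_obs = cfg$smoothing$min_obs)
          attr(s, "individual_id") <- id
          ph <- suppressMessages(segment_phases(s,
            decline_min = cfg$phases$decline_min,
            min_days = cfg$phases$min_days))
          rows[[id]] <- ph
          sl <- suppressMessages(departure_slope(
            data.frame(day = s$day, value = s$dr_raw), ph, "drift_rate"))
          if (!is.null(sl)) slr[[id]] <- sl
        }
        .fwrite(do.call(rbind, rows), file.path(out, "phases.csv"))
        if (length(slr)) .fwrite(do.call(rbind, slr),
                                 file.path(out, "slopes.csv"))
        .fwrite(compute_bmi(morph), file.path(out, "bmi.csv"))
      },
      adl = {
        ab <- read_abstracted_csv(.cli_arg(args, "--in",
                                           "dives_abstracted.csv"))
        phases <- .fread(.cli_arg(args, "--phases", "phases.csv"))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        thr <- do.call(tadl_thresholds, stats::setNames(
          cfg$tadl, sub("^return$", "return_", names(cfg$tadl))))
        tad <- tadl_exceedance(ab$dives, phases, thr)
        .fwrite(tad$by_individual, file.path(out, "tadl.csv"))
        badl <- fit_badl_breakpoint(ab$dives)
        jsonlite::write_json(badl[c("breakpoint", "slope_below",
                                    "slope_above", "diagnostic")],
                             file.path(out, "badl.json"),
                             auto_unbox = TRUE, digits = NA, na = "null")
        metrics <- .metrics_table(ab$dives, ab$segments)
        metrics$age_class <- "pooled"
        .fwrite(surface_relations(metrics, n_boot = cfg$adl$n_boot,
                                  seed = cfg$seed),
                file.path(out, "surface_relations.csv"))
      },
      report = ,
      all = {
        run_pipeline(cfg, out_dir = out, level = level)
      },
      stop("config error: unknown command '", cmd, "'")
    )
    0L
  }, error = function(e) {
    message("divekit: ", conditionMessage(e))
    if (grepl("config error", conditionMessage(e))) 3L else 2L
  })
  status
}
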