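# Delimited-text readers and writers for every pipeline schema, plus the
# YAML pipeline configuration. All files are comma-delimited, header row,
# UTF-8, '.' decimal. Internal units: seconds and metres; minutes appear
# only at the reporting boundary.

.fwrite <- function(x, path) data.table::fwrite(x, path)
.fread <- function(path) as.data.frame(data.table::fread(path))

#' Write a simulated cohort as raw CSV tables
#'
#' Emits the tag-level schemas: `dives.csv` (dive_id, individual_id, day,
#' t0, duration_s, surface_s), `profiles.csv` (dive_id, t_offset_s,
#' depth_m; only when 1-Hz profiles were simulated), `segments_accel.csv`
#' (dive_id, segment_idx, t_start_s, t_end_s, effort_sum, prca_s),
#' `morphometrics.csv`, `haulouts.csv` and -- synthetic records only --
#' `truth_daily.csv`, `truth_dives.csv`, `truth_individuals.csv`.
#'
#' @param cohort a `trip_cohort`.
#' @param dir output directory (created if needed).
#' @param profiles write the (potentially large) 1-Hz profile table?
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir, profiles = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dv <- do.call(rbind, lapply(cohort, `[[`, "dives"))
  .fwrite(data.frame(dive_id = dv$dive_id, individual_id = dv$individual_id,
                     day = dv$day, t0 = dv$t0_s,
                     duration_s = dv$duration_s, surface_s = dv$surface_s),
          file.path(dir, "dives.csv"))
  seg <- do.call(rbind, lapply(cohort, `[[`, "segments_true"))
  .fwrite(seg[c("dive_id", "segment_idx", "t_start_s", "t_end_s",
                "effort_sum", "prca_s")],
          file.path(dir, "segments_accel.csv"))
  mo <- cohort_morphometrics(cohort)
  .fwrite(data.frame(id = mo$individual_id, age_class = mo$age_class,
                     mass_kg = mo$mass_kg, length_cm = mo$length_cm,
                     deploy_day = mo$deploy_day,
                     departure_day = mo$departure_day),
          file.path(dir, "morphometrics.csv"))
  ho <- do.call(rbind, lapply(cohort, function(r)
    if (nrow(r$haul_outs)) cbind(individual_id = r$individual_id,
                                 r$haul_outs) else NULL))
  if (is.null(ho))
    ho <- data.frame(individual_id = character(0), start_day = numeric(0),
                     end_day = numeric(0))
  .fwrite(ho, file.path(dir, "haulouts.csv"))
  if (profiles && !is.null(cohort[[1]]$profiles)) {
    pr <- lapply(cohort, function(r) {
      len <- lengths(r$profiles)
      data.frame(dive_id = rep(names(r$profiles), len),
                 t_offset_s = unlist(lapply(len, function(l) 0:(l - 1L)),
                                     use.names = FALSE),
                 depth_m = unlist(r$profiles, use.names = FALSE))
    })
    .fwrite(do.call(rbind, pr), file.path(dir, "profiles.csv"))
  }
  .fwrite(do.call(rbind, lapply(cohort, function(r)
    cbind(individual_id = r$individual_id, r$truth$daily))),
    file.path(dir, "truth_daily.csv"))
  .fwrite(data.frame(dive_id = dv$dive_id, is_drift = dv$is_drift,
                     dr_true = dv$dr_true),
          file.path(dir, "truth_dives.csv"))
  .fwrite(do.call(rbind, lapply(cohort, function(r) data.frame(
    individual_id = r$individual_id,
    switch_day = if (is.na(r$truth$switch_day)) NA_real_ else
      r$truth$switch_day,
    phase1_end = r$truth$offsets$phase1_end,
    phase2_end = r$truth$offsets$phase2_end,
    dr_init = r$truth$offsets$dr_init,
    dead = r$truth$dead, end_day = r$truth$end_day))),
    file.path(dir, "truth_individuals.csv"))
  invisible(dir)
}

#' Read raw cohort CSV tables back into trip records
#'
#' Inverse of [write_cohort_csv()]; truth tables are attached when
#' present.
#'
#' @param dir directory holding the schema files.
#' @return a `trip_cohort` (profiles included when `profiles.csv` exists).
#' @export
read_cohort_csv <- function(dir) {
  dv <- .fread(file.path(dir, "dives.csv"))
  seg <- .fread(file.path(dir, "segments_accel.csv"))
  mo <- .fread(file.path(dir, "morphometrics.csv"))
  ho <- .fread(file.path(dir, "haulouts.csv"))
  prof_path <- file.path(dir, "profiles.csv")
  profs <- NULL
  if (file.exists(prof_path)) {
    pr <- .fread(prof_path)
    profs <- split(pr$depth_m, factor(pr$dive_id, levels = unique(pr$dive_id)))
  }
  td_path <- file.path(dir, "truth_daily.csv")
  truth_daily <- if (file.exists(td_path)) .fread(td_path) else NULL
  ti_path <- file.path(dir, "truth_individuals.csv")
  truth_ind <- if (file.exists(ti_path)) .fread(ti_path) else NULL
  tv_path <- file.path(dir, "truth_dives.csv")
  truth_dives <- if (file.exists(tv_path)) .fread(tv_path) else NULL

  cohort <- lapply(seq_len(nrow(mo)), function(i) {
    id <- mo$id[i]
    dvi <- dv[dv$individual_id == id, , drop = FALSE]
    names(dvi)[names(dvi) == "t0"] <- "t0_s"
    if (!is.null(truth_dives)) {
      mi <- match(dvi$dive_id, truth_dives$dive_id)
      dvi$is_drift <- truth_dives$is_drift[mi]
      dvi$dr_true <- truth_dives$dr_true[mi]
    }
    truth <- NULL
    if (!is.null(truth_daily)) {
      ti <- truth_ind[truth_ind$individual_id == id, , drop = FALSE]
      truth <- list(
        daily = truth_daily[truth_daily$individual_id == id,
                            c("day", "dr_true"), drop = FALSE],
        switch_day = ti$switch_day, dead = ti$dead, end_day = ti$end_day,
        offsets = list(phase1_end = ti$phase1_end,
                       phase2_end = ti$phase2_end, dr_init = ti$dr_init))
    }
    structure(list(
      individual_id = id, age_class = mo$age_class[i],
      morph = data.frame(individual_id = id, age_class = mo$age_class[i],
                         mass_kg = mo$mass_kg[i], length_cm = mo$length_cm[i],
                         deploy_day = mo$deploy_day[i],
                         departure_day = mo$departure_day[i]),
      dives = dvi,
      segments_true = seg[seg$dive_id %in% dvi$dive_id, , drop = FALSE],
      profiles = if (is.null(profs)) NULL else profs[dvi$dive_id],
      haul_outs = ho[ho$individual_id == id,
                     c("start_day", "end_day"), drop = FALSE],
      truth = truth
    ), class = "trip_record")
  })
  names(cohort) <- mo$id
  structure(cohort, class = "trip_cohort")
}

#' Write / read the abstracted-dive table
#'
#' Single CSV holding one row per dive (`row_type = "dive"`) plus one row
#' per segment (`row_type = "segment"`); round-trips losslessly through
#' [read_abstracted_csv()].
#'
#' @param abst list with `dives` and `segments` from [abstract_cohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_abstracted_csv <- function(abst, path) {
  dv <- abst$dives
  seg <- abst$segments
  dive_part <- data.frame(
    row_type = "dive", dive_id = dv$dive_id,
    individual_id = dv$individual_id, day = dv$day,
    max_depth_m = dv$max_depth_m, duration_s = dv$duration_s,
    surface_s = dv$surface_s,
    segment_idx = NA_integer_, role = NA_character_,
    t_start_s = NA_real_, t_end_s = NA_real_,
    depth_start_m = NA_real_, depth_end_m = NA_real_,
    vertical_rate = NA_real_, effort_sum = NA_real_,
    effort_rate = NA_real_, prca_fraction = NA_real_)
  seg_part <- data.frame(
    row_type = "segment", dive_id = seg$dive_id,
    individual_id = NA_character_, day = NA_real_,
    max_depth_m = NA_real_, duration_s = NA_real_, surface_s = NA_real_,
    segment_idx = seg$segment_idx, role = seg$role,
    t_start_s = seg$t_start_s, t_end_s = seg$t_end_s,
    depth_start_m = seg$depth_start_m, depth_end_m = seg$depth_end_m,
    vertical_rate = seg$vertical_rate, effort_sum = seg$effort_sum,
    effort_rate = seg$effort_rate, prca_fraction = seg$prca_fraction)
  .fwrite(rbind(dive_part, seg_part), path)
  invisible(path)
}

#' @rdname write_abstracted_csv
#' @export
read_abstracted_csv <- function(path) {
  x <- .fread(path)
  dv <- x[x$row_type == "dive",
          c("dive_id", "individual_id", "day", "max_depth_m", "duration_s",
            "surface_s"), drop = FALSE]
  seg <- x[x$row_type == "segment",
           c("dive_id", "segment_idx", "t_start_s", "t_end_s",
             "depth_start_m", "depth_end_m", "vertical_rate", "effort_sum",
             "effort_rate", "prca_fraction", "role"), drop = FALSE]
  rownames(dv) <- rownames(seg) <- NULL
  list(dives = dv, segments = seg)
}

#' Default pipeline configuration
#'
#' Nested list mirroring the tunable surface of the pipeline: generator
#' parameter blocks per cohort, drift-filter thresholds, smoothing window,
#' phase mode, tADL thresholds and the analysis seeds. Serialises to YAML
#' via [write_config()] and round-trips unchanged.
#'
#' @param seed master seed applied to every cohort and to the bootstrap.
#' @param cohorts character subset of `c("juvenile", "adult")`.
#' @return a `divekit_config` list.
#' @export
default_config <- function(seed = 1L, cohorts = c("juvenile", "adult")) {
  cohorts <- match.arg(cohorts, several.ok = TRUE)
  cfg <- list(
    seed = as.integer(seed),
    cohorts = lapply(stats::setNames(cohorts, cohorts), function(ac)
      unclass(generator_params(ac, seed = seed))),
    filter = drift_filter_control(),
    smoothing = list(window = 7L, min_obs = 3L),
    phases = list(mode = "detected", decline_min = 0.02, min_days = 30L),
    tadl = tadl_thresholds(),
    adl = list(extended_cutoff_min = 3.5, n_boot = 1000L)
  )
  class(cfg) <- "divekit_config"
  cfg
}

#' Read / write a pipeline configuration (YAML)
#' @param path YAML file.
#' @return for `read_config()`, a `divekit_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed) || is.null(cfg$cohorts))
    stop("config error: 'seed' and 'cohorts' blocks are required")
  base <- default_config(seed = cfg$seed,
                         cohorts = names(cfg$cohorts))
  for (blk in c("filter", "smoothing", "phases", "tadl", "adl"))
    if (!is.null(cfg[[blk]]))
      base[[blk]] <- .merge_typed(base[[blk]], cfg[[blk]])
  for (ac in names(cfg$cohorts)) {
    ov <- cfg$cohorts[[ac]]
    unknown <- setdiff(names(ov), c(names(base$cohorts[[ac]])))
    if (length(unknown))
      stop("config error: unknown generator parameter(s) for ", ac, ": ",
           paste(unknown, collapse = ", "))
    base$cohorts[[ac]] <- .merge_typed(base$cohorts[[ac]], ov)
  }
  base
}

# Merge overrides into a template, matching the template's storage type so
# a write -> read cycle is the identity (YAML drops the int/double
# distinction).
.merge_typed <- function(template, overrides) {
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    d <- template[[nm]]
    if (is.double(d) && is.integer(v)) v <- as.double(v)
    if (is.integer(d) && is.double(v) && !is.na(v) && v == round(v))
      v <- as.integer(v)
    template[nm] <- list(v)
  }
  template
}

#' @rdname read_config
#' @param config a `divekit_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
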