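# CSV schemas, configuration round-trips, pipeline report, CLI dispatcher.

test_that("cohort CSV schemas round-trip losslessly", {
  p <- small_juvenile_params(seed = 51, n = 2, days = 12)
  co <- simulate_cohort(p, level = "profile")
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("dives.csv", "profiles.csv", "segments_accel.csv",
      "morphometrics.csv", "haulouts.csv", "truth_daily.csv",
      "truth_dives.csv", "truth_individuals.csv")))))
  back <- read_cohort_csv(dir)
  expect_equal(names(back), names(co))
  for (id in names(co)) {
    expect_equal(back[[id]]$dives$duration_s, co[[id]]$dives$duration_s)
    expect_equal(back[[id]]$dives$surface_s, co[[id]]$dives$surface_s)
    expect_equal(back[[id]]$morph$mass_kg, co[[id]]$morph$mass_kg)
    expect_equal(unname(unlist(back[[id]]$profiles)),
                 unname(unlist(co[[id]]$profiles)))
    expect_equal(back[[id]]$segments_true$effort_sum,
                 co[[id]]$segments_true$effort_sum)
    expect_equal(back[[id]]$truth$daily$dr_true, co[[id]]$truth$daily$dr_true)
  }
})

test_that("abstracted-dive table round-trips losslessly", {
  p <- small_juvenile_params(seed = 53, n = 1, days = 6)
  ab <- abstract_cohort(simulate_cohort(p, level = "profile"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_abstracted_csv(ab, path)
  back <- read_abstracted_csv(path)
  expect_equal(back$dives$dive_id, ab$dives$dive_id)
  expect_equal(back$dives$max_depth_m, ab$dives$max_depth_m)
  expect_equal(back$segments$vertical_rate, ab$segments$vertical_rate)
  expect_equal(back$segments$prca_fraction, ab$segments$prca_fraction)
  expect_equal(back$segments$role, ab$segments$role)
})

test_that("configuration round-trips through YAML unchanged", {
  cfg <- default_config(seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(unclass(back), unclass(cfg))
  # every filter default equals its published threshold
  expect_equal(cfg$filter$effort_max, 4)
  expect_equal(cfg$filter$rate_min, -0.3)
  expect_equal(cfg$filter$rate_max, 0.6)
  expect_equal(cfg$filter$min_fraction, 0.40)
  expect_equal(cfg$tadl, list(departure = 6, central = 10, return = 18,
                              adult = 28))
  expect_error(read_config(withr::local_tempfile(lines = "cohorts: {}")),
               "config error")
})

test_that("pipeline report is deterministic for a fixed seed", {
  cfg <- default_config(seed = 77, cohorts = "juvenile")
  cfg$cohorts$juvenile$n_individuals <- 3L
  cfg$cohorts$juvenile$trip_days_max <- 60
  cfg$cohorts$juvenile$tag_end_min <- 59
  cfg$cohorts$juvenile$tag_death_frac <- 0
  cfg$adl$n_boot <- 50L
  r1 <- run_pipeline(cfg, level = "segment")
  r2 <- run_pipeline(cfg, level = "segment")
  expect_identical(report_text(r1), report_text(r2))
  expect_identical(report_summary(r1), report_summary(r2))
  # report carries every cohort statistic block
  co <- r1$cohorts$juvenile
  expect_true(all(c("dive_duration_min", "surface_min_by_individual",
                    "max_depth_m", "switch_day", "initial_drift_rate",
                    "tadl", "extended_surface_fraction", "badl",
                    "surface_relations", "filter_drops") %in% names(co)))
  expect_equal(co$n_individuals, 3L)
  for (s in co[c("dive_duration_min", "max_depth_m")])
    expect_true(is.finite(s$mean) && is.finite(s$sd) && s$n > 0)
})

test_that("pipeline writes its output tables and report files", {
  cfg <- default_config(seed = 78, cohorts = "juvenile")
  cfg$cohorts$juvenile$n_individuals <- 3L
  cfg$cohorts$juvenile$trip_days_max <- 60
  cfg$cohorts$juvenile$tag_end_min <- 59
  cfg$cohorts$juvenile$tag_death_frac <- 0
  cfg$adl$n_boot <- 20L
  out <- withr::local_tempdir()
  run_pipeline(cfg, out_dir = out, level = "segment")
  expect_true(all(file.exists(file.path(out, "juvenile",
    c("dives_abstracted.csv", "drift.csv", "phases.csv", "bmi.csv",
      "tadl.csv", "badl.json", "surface_relations.csv")))))
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "report.txt")))
  js <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(js$seed, 78L)
  expect_true("juvenile" %in% names(js$cohorts))
})

test_that("CLI dispatcher chains the pipeline stages over CSV files", {
  dir <- withr::local_tempdir()
  cfg <- default_config(seed = 91, cohorts = "juvenile")
  cfg$cohorts$juvenile$n_individuals <- 3L
  cfg$cohorts$juvenile$trip_days_max <- 70
  cfg$cohorts$juvenile$tag_end_min <- 69
  cfg$cohorts$juvenile$tag_death_frac <- 0
  cfg$adl$n_boot <- 10L
  cfg_path <- file.path(dir, "config.yaml")
  write_config(cfg, cfg_path)
  raw <- file.path(dir, "raw")
  expect_equal(divekit_main(c("simulate", "--config", cfg_path,
                              "--seed", "91", "--out", raw)), 0L)
  expect_true(file.exists(file.path(raw, "juvenile", "dives.csv")))
  expect_equal(divekit_main(c("abstract", "--in",
                              file.path(raw, "juvenile"),
                              "--out", dir)), 0L)
  expect_equal(divekit_main(c("drift", "--in",
                              file.path(dir, "dives_abstracted.csv"),
                              "--out", dir)), 0L)
  expect_equal(divekit_main(c("condition",
                              "--drift", file.path(dir, "drift.csv"),
                              "--morph", file.path(raw, "juvenile",
                                                   "morphometrics.csv"),
                              "--out", dir)), 0L)
  expect_equal(divekit_main(c("adl", "--config", cfg_path,
                              "--in", file.path(dir, "dives_abstracted.csv"),
                              "--phases", file.path(dir, "phases.csv"),
                              "--out", dir)), 0L)
  expect_true(all(file.exists(file.path(dir,
    c("drift.csv", "phases.csv", "bmi.csv", "tadl.csv", "badl.json")))))
  # drift.csv estimates agree with the in-memory path
  ab <- read_abstracted_csv(file.path(dir, "dives_abstracted.csv"))
  est_file <- data.table::fread(file.path(dir, "drift.csv"))
  est_mem <- drift_estimates(ab$dives, ab$segments)
  expect_equal(est_file$drift_rate, est_mem$drift_rate)
  # unknown command and broken config are distinct failures
  expect_equal(divekit_main("frobnicate"), 3L)
  expect_equal(divekit_main(c("drift", "--in", "no-such-file.csv")), 2L)
})
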