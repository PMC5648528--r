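fixture_experiment <- function(n_flies = 4, days = 2, seed = 7) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  make_fixtures(dir, seed = seed, n_flies = n_flies, days = days)
}

test_that("config files validate inputs and fill defaults", {
  fx <- fixture_experiment()
  cfg <- read_experiment_config(fx$config)
  expect_s3_class(cfg$schedule_obj, "light_schedule")
  expect_equal(cfg$params$min_bout, 5)
  expect_equal(cfg$params$period_range, c(18, 30))
  expect_true(file.exists(cfg$input$path))
  expect_error(read_experiment_config("/nonexistent.yaml"), "not found")
})

test_that("score command writes bout, metrics and profile tables", {
  fx <- fixture_experiment()
  out <- withr::local_tempdir()
  res <- cmd_score(fx$config, out)
  expect_true(all(file.exists(file.path(out,
    c("bouts.csv", "metrics.csv", "profile_wt.csv", "run_log.yaml")))))
  m <- read.csv(file.path(out, "metrics.csv"))
  expect_setequal(unique(m$label), c("day", "night"))
  expect_equal(length(unique(m$fly_id)), 4)
  # night sleep dominates day sleep in the wild-type fixture
  expect_gt(mean(m$total_sleep_min[m$label == "night"]),
            mean(m$total_sleep_min[m$label == "day"]))
  # rerun is byte-identical (determinism of the full path)
  out2 <- withr::local_tempdir()
  cmd_score(fx$config, out2)
  expect_identical(readLines(file.path(out, "bouts.csv")),
                   readLines(file.path(out2, "bouts.csv")))
})

test_that("misconfigured groups fail with the offending channel named", {
  fx <- fixture_experiment()
  cfg <- read_experiment_config(fx$config)
  cfg$groups <- list(wt = c(1, 99))
  out <- withr::local_tempdir()
  expect_error(cmd_score(cfg, out), "99")
})

test_that("simulate -> score round trip runs end to end", {
  fx <- fixture_experiment()
  cfg <- read_experiment_config(fx$config)
  sim_out <- withr::local_tempdir()
  coh <- cmd_simulate(cfg, sim_out, seed = 11)
  expect_true(file.exists(file.path(sim_out, "Monitor1.txt")))
  cfg2 <- read_experiment_config(file.path(sim_out, "experiment.yaml"))
  score_out <- withr::local_tempdir()
  res <- cmd_score(cfg2, score_out)
  expect_true(file.exists(file.path(score_out, "metrics.csv")))
  # scored totals agree with the simulator's latent truth to within the
  # scoring rule's tolerance
  truth <- read.csv(file.path(sim_out, "truth.csv"))
  m <- read.csv(file.path(score_out, "metrics.csv"))
  expect_equal(sum(m$total_sleep_min) / sum(truth$latent_sleep_min), 1,
               tolerance = 0.15)
})

test_that("rebound command reports efficiency, curves and exclusions", {
  dir <- withr::local_tempdir()
  sched <- light_schedule()
  params <- sim_params(n_flies = 6, days = 4, seed = 13)
  t0 <- as.POSIXct("2024-01-01", tz = "UTC") + sched$lights_on
  set.seed(13)
  design <- deprivation_design(t0 + 36 * 3600)
  coh <- simulate_cohort(params, c(wt = 6), sched, protocol = design)
  write_dam_monitor(coh$traces, file.path(dir, "Monitor1.txt"))
  cfg <- list(input = list(format = "dam", path = "Monitor1.txt"),
              schedule = list(lights_on = "09:00", lights_off = "21:00",
                              mode = "LD"),
              groups = list(wt = 1:6),
              deprivation = list(start = "2024-01-02 21:00:00",
                                 seed = 13))
  yaml::write_yaml(cfg, file.path(dir, "exp.yaml"))
  out <- withr::local_tempdir()
  res <- cmd_rebound(file.path(dir, "exp.yaml"), out)
  flies <- read.csv(file.path(out, "rebound_flies.csv"))
  expect_equal(nrow(flies), 6)
  expect_true(mean(flies$efficiency, na.rm = TRUE) > 90)
  expect_true(file.exists(file.path(out, "rebound_curves.csv")))
  expect_true(file.exists(file.path(out, "rebound_group.csv")))
  # both loss conventions present
  expect_true(all(c("lost_min", "lost_min_strict") %in% names(flies)))
})

test_that("period command flags constant channels arrhythmic", {
  dir <- withr::local_tempdir()
  sched <- light_schedule(mode = "DD")
  t0 <- as.POSIXct("2024-01-01 09:00", tz = "UTC")
  rhythmic <- activity_trace("r", t0, 60,
                             rep(c(rep(6, 720), rep(0, 720)), 12), sched)
  flat <- activity_trace("f", t0, 60, rep(0, 12 * 1440), sched)
  write_dam_monitor(c(rep(list(rhythmic), 2), list(flat)),
                    file.path(dir, "Monitor1.txt"))
  yaml::write_yaml(list(
    input = list(format = "dam", path = "Monitor1.txt"),
    schedule = list(mode = "DD"),
    groups = list(wt = 1:3)), file.path(dir, "exp.yaml"))
  out <- withr::local_tempdir()
  res <- cmd_period(file.path(dir, "exp.yaml"), out)
  per <- read.csv(file.path(out, "periods.csv"))
  expect_equal(per$period_h[1:2], c(24, 24))
  expect_true(per$arrhythmic[3])
  expect_equal(res$n_arrhythmic, 1)
})
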