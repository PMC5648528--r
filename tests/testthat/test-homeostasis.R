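dep_start <- T0 + 36 * 3600           # lights-off of the second day

test_that("deprivation efficiency follows its defining ratio", {
  expect_equal(deprivation_efficiency(600, 0), 100)
  expect_equal(deprivation_efficiency(600, 60), 90)
  expect_equal(deprivation_efficiency(c(600, 0), c(30, 10)),
               c(95, NA))
  # 100% iff no sleep survived deprivation
  expect_true(deprivation_efficiency(480, 0) == 100)
  expect_true(deprivation_efficiency(480, 1e-9) < 100)
})

test_that("both sleep-loss conventions are exposed and coincide under
           complete deprivation", {
  expect_equal(sleep_lost(600, 0), 600)
  expect_equal(sleep_lost(600, 50), 550)
  expect_equal(sleep_lost(600, 50, mode = "baseline"), 600)
  base <- runif(20, 200, 700)
  expect_equal(sleep_lost(base, 0), sleep_lost(base, 0, "baseline"))
  # negative loss is returned as-is
  expect_equal(sleep_lost(300, 400), -100)
})

test_that("a deprivation design holds a valid 20 s / 3 min schedule", {
  set.seed(1)
  d <- deprivation_design(dep_start)
  expect_equal(nrow(d$epochs), 12 * 3600 / 180)
  expect_true(all(d$epochs$start >= d$dep_start))
  expect_true(all(d$epochs$end <= d$dep_end))
  durs <- as.numeric(d$epochs$end) - as.numeric(d$epochs$start)
  expect_true(all(durs == 20))
  # one epoch per cycle, inside its own cycle
  cyc <- floor((as.numeric(d$epochs$start) - as.numeric(dep_start)) / 180)
  expect_equal(cyc, 0:239)
  # every inter-stimulus gap is shorter than the 5-min sleep threshold
  gaps <- as.numeric(d$epochs$start[-1]) - as.numeric(d$epochs$end[-240])
  expect_true(all(gaps < 300))
})

# helper: fabricate bout objects with one bout per hourly block
hourly_bouts <- function(t0, sleep_min_per_h) {
  onsets <- t0 + (seq_along(sleep_min_per_h) - 1) * 3600
  keep <- sleep_min_per_h > 0
  structure(data.frame(onset = onsets[keep],
                       duration_min = sleep_min_per_h[keep],
                       phase_at_onset = "D"),
            class = c("sleep_bouts", "data.frame"), fly_id = "fab",
            t0 = t0, dt = 60,
            n_samples = length(sleep_min_per_h) * 60, min_bout = 5,
            n_missing = 0)
}

test_that("rebound is zero when recovery reproduces baseline and scales
           as cumulative excess over the clock-matched hours", {
  b0 <- T0 - 24 * 3600
  base <- hourly_bouts(b0, rep(20, 24))
  same <- hourly_bouts(T0, rep(20, 24))
  cu <- rebound_curve(base, same, lost = 600, baseline_start = b0,
                      recovery_start = T0)
  expect_true(all(cu$cum_percent == 0))
  # constant +25 min/h excess over lost 600 -> exactly 100% at h = 24
  extra <- hourly_bouts(T0, rep(45, 24))
  cu2 <- rebound_curve(base, extra, lost = 600, baseline_start = b0,
                       recovery_start = T0)
  expect_equal(attr(cu2, "recovered_24h"), 100)
  expect_equal(cu2$cum_percent, 100 * cumsum(rep(25, 24)) / 600)
  expect_error(rebound_curve(base, extra, lost = 0,
                             baseline_start = b0, recovery_start = T0),
               "positive")
})

test_that("hourly rebound values are cumulative and shift-invariant", {
  set.seed(31)
  b0 <- T0 - 24 * 3600
  base_h <- sample(0:40, 24, replace = TRUE)
  rec_h <- sample(0:40, 24, replace = TRUE)
  cu <- rebound_curve(hourly_bouts(b0, base_h), hourly_bouts(T0, rec_h),
                      lost = 300, baseline_start = b0, recovery_start = T0)
  # differences of the cumulative curve reconstruct per-hour excess
  expect_equal(diff(c(0, cu$regained_min)), rec_h - base_h)
  # adding the same constant to every baseline and recovery hour
  cu2 <- rebound_curve(hourly_bouts(b0, base_h + 10),
                       hourly_bouts(T0, rec_h + 10),
                       lost = 300, baseline_start = b0, recovery_start = T0)
  expect_equal(cu$cum_percent, cu2$cum_percent)
})

test_that("clock-matching pairs recovery hours with same-time baseline hours", {
  # recovery starts 12 h after the baseline day starts: hour 1 of recovery
  # must be compared against baseline hour 13
  b0 <- T0 - 12 * 3600
  base_h <- c(rep(0, 12), 30, rep(0, 11))       # 30 min at baseline hour 13
  rec <- hourly_bouts(T0, c(30, rep(0, 23)))    # same clock time, same sleep
  cu <- rebound_curve(hourly_bouts(b0, base_h), rec, lost = 100,
                      baseline_start = b0, recovery_start = T0)
  expect_equal(cu$cum_percent[1], 0)
})

test_that("group rebound averages curves and reports per-fly summaries", {
  b0 <- T0 - 24 * 3600
  base <- hourly_bouts(b0, rep(20, 24))
  mk <- function(extra) rebound_curve(base, hourly_bouts(T0, rep(20 + extra, 24)),
                                      lost = 600, baseline_start = b0,
                                      recovery_start = T0)
  g <- group_rebound(list(mk(25), mk(25)))
  expect_true(all(g$curve$sem_percent == 0))
  expect_equal(attr(g$recovered_24h, "mean"), 100)
  # one fly at 0%, one at 100% -> mean 50%
  g2 <- group_rebound(list(mk(0), mk(25)))
  expect_equal(attr(g2$recovered_24h, "mean"), 50)
  expect_error(group_rebound(list()), "no curves")
})

test_that("cohort rebound analysis applies exclusion rules with reasons", {
  set.seed(77)
  design <- deprivation_design(dep_start, horizon_h = 24)
  params <- sim_params(days = 4, seed = 404)
  coh <- simulate_cohort(params, c(wt = 6), protocol = design)
  # corrupt one fly: no data at all in the baseline night
  coh$traces[[1]]$values[] <- 2                         # never immobile
  coh$traces[[2]]$values[1:3000] <- NA                  # low coverage
  res <- rebound_analysis(coh$traces, design)
  expect_equal(res$flies$reason[1], "baseline_zero")
  expect_equal(res$flies$reason[2], "low_coverage")
  expect_true(all(is.na(res$flies$reason[3:6])))
  expect_length(res$curves, 4)
  expect_equal(nrow(res$group$curve), 24)
  # efficiency is ~100% under the forced-wake night for scored flies
  expect_true(all(res$flies$efficiency[3:6] > 95))
})
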