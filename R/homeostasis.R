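# Sleep-deprivation efficiency and homeostatic rebound. The rebound readout
# is the hourly cumulative percentage of lost sleep regained over the
# recovery period, each recovery hour referenced to the fly's own
# clock-matched baseline hour (the 24 h preceding deprivation).

#' Mechanical sleep-deprivation design
#'
#' Describes a deprivation experiment: the 12-h deprivation window (normally
#' the night), its clock-matched 24-h baseline, the stimulation schedule
#' (one 20-s forced-wake epoch per 3-min cycle, at a random phase within
#' each cycle — the standard shaker protocol), and the recovery horizon.
#' Stimulus epoch phases are drawn from the current RNG stream, so set a
#' seed for a reproducible design.
#'
#' @param start POSIXct start of the deprivation window.
#' @param duration_h Deprivation duration in hours (default 12).
#' @param cycle_s Stimulation cycle length in seconds (default 180).
#' @param stim_s Stimulation duration per cycle in seconds (default 20).
#' @param horizon_h Recovery horizon in hours, 24 or 48 (default 24).
#' @return An object of class `deprivation_design` with an `epochs`
#'   data.frame (`start`, `end` POSIXct) of stimulation intervals.
#' @export
deprivation_design <- function(start, duration_h = 12, cycle_s = 180,
                               stim_s = 20, horizon_h = 24) {
  stopifnot(inherits(start, "POSIXct"), duration_h > 0,
            stim_s > 0, stim_s < cycle_s)
  n_cycles <- floor(duration_h * 3600 / cycle_s)
  phase <- stats::runif(n_cycles, 0, cycle_s - stim_s)
  e0 <- as.numeric(start) + (seq_len(n_cycles) - 1) * cycle_s + phase
  structure(list(
    baseline_start = start - 24 * 3600,
    dep_start = start,
    dep_end = start + duration_h * 3600,
    horizon_h = horizon_h, cycle_s = cycle_s, stim_s = stim_s,
    epochs = data.frame(
      start = as.POSIXct(e0, origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(e0 + stim_s, origin = "1970-01-01", tz = "UTC"))
  ), class = "deprivation_design")
}

#' Sleep-deprivation efficiency
#'
#' Percentage of baseline-night sleep eliminated during the deprivation
#' night: `100 * (1 - deprivation / baseline)`. 100% iff no sleep at all was
#' scored during deprivation.
#'
#' @param baseline_night_sleep,deprivation_night_sleep Minutes of scored
#'   sleep in the baseline and deprivation nights (vectorised).
#' @return Percent efficiency; `NA` where baseline is 0 (such flies are
#'   excluded with a reason code by [rebound_analysis()]).
#' @export
deprivation_efficiency <- function(baseline_night_sleep,
                                   deprivation_night_sleep) {
  ifelse(baseline_night_sleep > 0,
         100 * (1 - deprivation_night_sleep / baseline_night_sleep),
         NA_real_)
}

#' Sleep lost to deprivation
#'
#' Two conventions are exposed. `"difference"` (default): baseline-night
#' sleep minus sleep that survived deprivation. `"baseline"`: the whole
#' baseline-night sleep, i.e. the sleep the fly would have had. With
#' complete (100%-efficient) deprivation the two coincide.
#'
#' @param baseline_night_sleep,deprivation_night_sleep Minutes (vectorised).
#' @param mode `"difference"` or `"baseline"`.
#' @return Minutes lost. May be negative (fly slept more during deprivation
#'   than baseline); negative values are returned as-is and flagged by
#'   [rebound_analysis()].
#' @export
sleep_lost <- function(baseline_night_sleep, deprivation_night_sleep,
                       mode = c("difference", "baseline")) {
  mode <- match.arg(mode)
  switch(mode,
         difference = baseline_night_sleep - deprivation_night_sleep,
         baseline = baseline_night_sleep)
}

# sleep minutes in consecutive 1-h bins of [from, from + hours*3600)
hourly_sleep <- function(bouts, from, hours) {
  vapply(seq_len(hours), function(h)
    bout_overlap_min(bouts, from + (h - 1) * 3600, from + h * 3600), 0)
}

#' Hourly cumulative rebound curve for one fly
#'
#' For each recovery hour h, sleep regained is the cumulative sum over hours
#' 1..h of (sleep in recovery hour k minus sleep in the clock-matched
#' baseline hour), expressed as a percentage of the sleep lost. Values are
#' not clamped: negative rebound and overshoot beyond 100% are meaningful.
#'
#' @param baseline_bouts Bouts covering the 24 h before deprivation.
#' @param recovery_bouts Bouts covering `horizon_h` hours after deprivation
#'   end (may be the same scored object if one trace spans the experiment).
#' @param lost Minutes of sleep lost (> 0); see [sleep_lost()].
#' @param baseline_start POSIXct start of the 24-h baseline day.
#' @param recovery_start POSIXct end of deprivation / start of recovery.
#' @param horizon_h Recovery horizon in hours.
#' @return An object of class `rebound_curve`: data.frame with `h`,
#'   `recovery_min`, `baseline_min`, `regained_min` (cumulative),
#'   `cum_percent`; attributes `fly_id`, `lost_min`, `recovered_24h`.
#' @export
rebound_curve <- function(baseline_bouts, recovery_bouts, lost,
                          baseline_start, recovery_start, horizon_h = 24) {
  if (!is.finite(lost) || lost <= 0)
    stop("lost must be a positive number of minutes")
  base_h <- hourly_sleep(baseline_bouts, baseline_start, 24)
  rec_h <- hourly_sleep(recovery_bouts, recovery_start, horizon_h)
  # clock-match: recovery hour starting at clock time c is compared with the
  # baseline hour starting at the same clock time
  offset_h <- ((as.numeric(recovery_start) - as.numeric(baseline_start)) /
                 3600) %% 24
  match_idx <- ((seq_len(horizon_h) - 1 + offset_h) %% 24) + 1
  regained <- cumsum(rec_h - base_h[match_idx])
  df <- data.frame(h = seq_len(horizon_h), recovery_min = rec_h,
                   baseline_min = base_h[match_idx],
                   regained_min = regained,
                   cum_percent = 100 * regained / lost)
  structure(df, class = c("rebound_curve", "data.frame"),
            fly_id = attr(recovery_bouts, "fly_id"), lost_min = lost,
            recovered_24h = if (horizon_h >= 24) df$cum_percent[24]
                            else NA_real_)
}

#' Cohort mean rebound curve
#'
#' Pointwise mean and SEM of individual cumulative-percent curves, plus the
#' 24-h recovery summary.
#'
#' @param curves List of [rebound_curve()] objects with equal horizons.
#' @return List with `curve` (data.frame `h`, `mean_percent`, `sem_percent`,
#'   `n`) and `recovered_24h` (data.frame `fly_id`, `percent` plus mean/sem
#'   attributes).
#' @export
group_rebound <- function(curves) {
  if (length(curves) == 0) stop("no curves to average")
  hs <- vapply(curves, nrow, 0L)
  if (length(unique(hs)) != 1) stop("curves have unequal horizons")
  m <- vapply(curves, function(cu) cu$cum_percent, numeric(hs[1]))
  m <- matrix(m, ncol = length(curves))
  r24 <- data.frame(
    fly_id = vapply(curves, function(cu) attr(cu, "fly_id"), ""),
    percent = vapply(curves, function(cu) attr(cu, "recovered_24h"), 0))
  list(curve = data.frame(h = seq_len(hs[1]),
                          mean_percent = rowMeans(m),
                          sem_percent = apply(m, 1, stats::sd) /
                            sqrt(ncol(m)),
                          n = ncol(m)),
       recovered_24h = structure(r24, mean = mean(r24$percent),
                                 sem = stats::sd(r24$percent) /
                                   sqrt(nrow(r24))))
}

#' Full per-fly deprivation/rebound analysis for a cohort
#'
#' Scores each trace, computes baseline- and deprivation-night sleep,
#' deprivation efficiency, sleep lost and the hourly rebound curve, applying
#' the per-fly exclusion rules with machine-readable reason codes:
#' `baseline_zero` (no baseline-night sleep), `nonpositive_loss`, and
#' `low_coverage` (< 90% data over the analysis span).
#'
#' @param traces List of [activity_trace()] spanning baseline day,
#'   deprivation window and recovery horizon.
#' @param design A [deprivation_design()].
#' @param min_bout Immobility threshold in minutes passed to
#'   [detect_sleep_bouts()].
#' @param loss_mode Passed to [sleep_lost()].
#' @param min_coverage Minimum data coverage to keep a fly (default 0.9).
#' @return List: `flies` (per-fly summary data.frame with `fly_id`,
#'   `baseline_night_min`, `deprivation_night_min`, `efficiency`,
#'   `lost_min`, `recovered_24h`, `excluded`, `reason`), `curves` (list of
#'   [rebound_curve()] for included flies), `group` ([group_rebound()]
#'   result or NULL if no fly survives exclusion).
#' @export
rebound_analysis <- function(traces, design, min_bout = 5,
                             loss_mode = c("difference", "baseline"),
                             min_coverage = 0.9) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(inherits(design, "deprivation_design"))
  b0 <- design$baseline_start
  dep_night_start <- design$dep_start
  rec_start <- design$dep_end
  rec_end <- rec_start + design$horizon_h * 3600
  # baseline *night*: the 12 h of the baseline day clock-matched to the
  # deprivation window
  base_night_start <- dep_night_start - 24 * 3600
  dep_len <- as.numeric(design$dep_end) - as.numeric(design$dep_start)

  rows <- list(); curves <- list()
  for (tr in traces) {
    bouts <- detect_sleep_bouts(tr, min_bout = min_bout)
    cov_span <- (as.numeric(rec_end) - as.numeric(b0)) / 60
    miss <- sample_weighted(tr, b0, rec_end,
                            function(v) as.numeric(is.na(v))) * tr$dt / 60
    coverage <- 1 - miss / cov_span
    base_night <- bout_overlap_min(bouts, base_night_start,
                                   base_night_start + dep_len)
    dep_night <- bout_overlap_min(bouts, design$dep_start, design$dep_end)
    eff <- deprivation_efficiency(base_night, dep_night)
    lost <- sleep_lost(base_night, dep_night, loss_mode)
    reason <- if (coverage < min_coverage) "low_coverage"
              else if (base_night <= 0) "baseline_zero"
              else if (lost <= 0) "nonpositive_loss"
              else NA_character_
    r24 <- NA_real_
    if (is.na(reason)) {
      cu <- rebound_curve(bouts, bouts, lost, b0, rec_start,
                          design$horizon_h)
      curves[[length(curves) + 1]] <- cu
      r24 <- attr(cu, "recovered_24h")
    }
    rows[[length(rows) + 1]] <- data.frame(
      fly_id = tr$fly_id, baseline_night_min = base_night,
      deprivation_night_min = dep_night, efficiency = eff,
      lost_min = lost, recovered_24h = r24,
      excluded = !is.na(reason), reason = reason,
      stringsAsFactors = FALSE)
  }
  flies <- do.call(rbind, rows)
  list(flies = flies, curves = curves,
       group = if (length(curves)) group_rebound(curves) else NULL)
}
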