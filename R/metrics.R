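# Per-fly sleep parameters over analysis windows. The study's convention:
# sleep duration, bout duration, latency and waking activity are reported
# for each 12-h light/dark (or subjective) phase. Sleep *time* in a window
# is raster overlap; bout count and mean duration attribute each whole bout
# to the window containing its onset.

# minutes of overlap between bouts and [from, to)
bout_overlap_min <- function(bouts, from, to) {
  if (nrow(bouts) == 0) return(0)
  b0 <- as.numeric(bouts$onset)
  b1 <- b0 + bouts$duration_min * 60
  sum(pmax(pmin(b1, as.numeric(to)) - pmax(b0, as.numeric(from)), 0)) / 60
}

# sample-weighted sum of f(values) over [from, to), weights = fractional
# overlap of each sample bin with the window (exactly additive over
# adjacent windows)
sample_weighted <- function(trace, from, to, f = identity) {
  t0 <- as.numeric(trace$t0); dt <- trace$dt
  a <- as.numeric(from); b <- as.numeric(to)
  i0 <- max(1L, floor((a - t0) / dt) + 1L)
  i1 <- min(length(trace$values), ceiling((b - t0) / dt))
  if (i1 < i0) return(0)
  idx <- i0:i1
  lo <- t0 + (idx - 1) * dt
  w <- (pmin(lo + dt, b) - pmax(lo, a)) / dt
  sum(f(trace$values[idx]) * w)
}

#' Sleep metrics for one fly over one analysis window
#'
#' Computes the standard per-window sleep parameters: total sleep (minutes of
#' bout overlap with the window), bout count and mean bout duration (bouts
#' with onset inside the window), waking activity (total movement divided by
#' minutes spent awake — locomotor distance or beam counts per waking
#' minute), data coverage, and, for night windows, sleep latency after
#' lights-off.
#'
#' @param bouts A [detect_sleep_bouts()] result.
#' @param trace The source [activity_trace()].
#' @param from,to POSIXct window bounds (within the trace span).
#' @param label Window label, e.g. `"day"`, `"night"`, `"24h"`. Latency is
#'   computed when the label is `"night"`, taking `from` as lights-off.
#' @return One-row data.frame: `fly_id`, `label`, `start`, `end`,
#'   `total_sleep_min`, `bout_count`, `mean_bout_min` (NA when no bout),
#'   `latency_min`/`latency_censored` (NA outside night windows),
#'   `waking_activity` (NA when no waking time), `movement_total`,
#'   `waking_min`, `missing_min`, `coverage`.
#' @export
window_metrics <- function(bouts, trace, from, to, label = NA_character_) {
  stopifnot(inherits(bouts, "sleep_bouts"), inherits(trace, "activity_trace"))
  if (!(as.numeric(to) > as.numeric(from))) stop("zero-length window")
  win_min <- (as.numeric(to) - as.numeric(from)) / 60
  sleep_min <- bout_overlap_min(bouts, from, to)
  onset_in <- bouts$onset >= from & bouts$onset < to
  n_bouts <- sum(onset_in)
  mean_bout <- if (n_bouts > 0) mean(bouts$duration_min[onset_in]) else NA_real_
  missing_min <- sample_weighted(trace, from, to,
                                 function(v) as.numeric(is.na(v))) *
    trace$dt / 60
  movement <- sample_weighted(trace, from, to,
                              function(v) ifelse(is.na(v), 0, v))
  waking_min <- win_min - sleep_min - missing_min
  lat <- if (identical(label, "night")) sleep_latency(bouts, from, to)
         else data.frame(latency_min = NA_real_, censored = NA)
  data.frame(
    fly_id = attr(bouts, "fly_id"), label = label,
    start = from, end = to,
    total_sleep_min = sleep_min, bout_count = n_bouts,
    mean_bout_min = mean_bout,
    latency_min = lat$latency_min, latency_censored = lat$censored,
    waking_activity = if (waking_min > 1e-9) movement / waking_min
                      else NA_real_,
    movement_total = movement, waking_min = waking_min,
    missing_min = missing_min,
    coverage = 1 - missing_min / win_min,
    stringsAsFactors = FALSE
  )
}

#' Sleep latency after lights-off
#'
#' Time from lights-off to the onset of the first sleep bout. A bout already
#' ongoing at lights-off gives latency 0. If no bout starts before the end
#' of the window the latency is censored at the window length.
#'
#' @param bouts A [detect_sleep_bouts()] result.
#' @param lights_off POSIXct lights-off time.
#' @param window_end POSIXct end of the night window (censoring point);
#'   default 12 h after `lights_off`.
#' @return One-row data.frame `latency_min`, `censored`.
#' @export
sleep_latency <- function(bouts, lights_off, window_end = lights_off + 12 * 3600) {
  stopifnot(inherits(bouts, "sleep_bouts"))
  win_min <- (as.numeric(window_end) - as.numeric(lights_off)) / 60
  if (nrow(bouts) > 0) {
    b0 <- as.numeric(bouts$onset)
    b1 <- b0 + bouts$duration_min * 60
    t_off <- as.numeric(lights_off)
    if (any(b0 <= t_off & b1 > t_off))
      return(data.frame(latency_min = 0, censored = FALSE))
    nxt <- b0[b0 >= t_off & b0 < as.numeric(window_end)]
    if (length(nxt) > 0)
      return(data.frame(latency_min = (min(nxt) - t_off) / 60,
                        censored = FALSE))
  }
  data.frame(latency_min = win_min, censored = TRUE)
}

#' Per-phase metrics for a whole recording
#'
#' Convenience wrapper: partitions the trace span into day/night windows via
#' [phase_windows()] and computes [window_metrics()] for each.
#'
#' @param bouts,trace As in [window_metrics()].
#' @param schedule A [light_schedule()]; defaults to the trace's.
#' @param complete_only Drop windows shorter than the full phase (edges of
#'   the recording). Default TRUE.
#' @return Data.frame, one row per window, with `phase` and `cycle` columns.
#' @export
phase_metrics <- function(bouts, trace, schedule = trace$schedule,
                          complete_only = TRUE) {
  pw <- phase_windows(schedule, trace$t0, trace_end(trace))
  if (complete_only) {
    full <- (as.numeric(pw$end) - as.numeric(pw$start)) %in%
      c((schedule$lights_off - schedule$lights_on) %% 86400,
        86400 - (schedule$lights_off - schedule$lights_on) %% 86400)
    pw <- pw[full, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(seq_len(nrow(pw)), function(i)
    window_metrics(bouts, trace, pw$start[i], pw$end[i], pw$phase[i])))
  out$cycle <- pw$cycle
  out
}

#' Cohort sleep profile
#'
#' Mean and SEM across flies of sleep minutes per time bin — the standard
#' sleep-profile plot's underlying table. All flies must share the same
#' sampling grid and span.
#'
#' @param bout_list List of [detect_sleep_bouts()] results.
#' @param bin Bin width in minutes (default 30).
#' @return An object of class `sleep_profile`: data.frame with `bin_start`
#'   (POSIXct), `mean_min`, `sem_min`, `n`.
#' @export
sleep_profile <- function(bout_list, bin = 30) {
  if (length(bout_list) == 0) stop("empty cohort")
  t0s <- vapply(bout_list, function(b) as.numeric(attr(b, "t0")), 0)
  spans <- vapply(bout_list,
                  function(b) attr(b, "n_samples") * attr(b, "dt"), 0)
  if (length(unique(t0s)) != 1 || length(unique(spans)) != 1)
    stop("all flies must share t0 and span")
  rasters <- vapply(bout_list,
                    function(b) sleep_raster(b, dt = bin * 60) * bin,
                    numeric(ceiling(spans[1] / (bin * 60))))
  rasters <- matrix(rasters, ncol = length(bout_list))
  m <- rowMeans(rasters)
  s <- apply(rasters, 1, stats::sd) / sqrt(ncol(rasters))
  t0 <- as.POSIXct(t0s[1], origin = "1970-01-01", tz = "UTC")
  structure(data.frame(
    bin_start = t0 + (seq_along(m) - 1) * bin * 60,
    mean_min = m, sem_min = s, n = ncol(rasters)),
    class = c("sleep_profile", "data.frame"), bin = bin)
}

#' @export
plot.sleep_profile <- function(x, col = "steelblue", ...) {
  graphics::plot(x$bin_start, x$mean_min, type = "l", col = col, lwd = 2,
                 xlab = "time", ylab = sprintf("sleep (min / %g min)",
                                              attr(x, "bin")), ...)
  graphics::polygon(c(x$bin_start, rev(x$bin_start)),
                    c(x$mean_min - x$sem_min, rev(x$mean_min + x$sem_min)),
                    col = grDevices::adjustcolor(col, 0.3), border = NA)
  invisible(x)
}
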