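#' Uniformly sampled per-fly movement series
#'
#' The basic container of the package: one fly's movement magnitude per
#' sampling bin, either infrared beam-crossing counts per minute (DAM,
#' `dt = 60`) or locomotor distance in mm per second (video, `dt = 1`).
#' Missing samples (monitor errors, tracking dropouts) are `NA` and are
#' treated downstream as neither sleep nor wake.
#'
#' @param fly_id Character identifier.
#' @param t0 POSIXct time of the first sample (UTC; the package does
#'   timezone-free clock arithmetic throughout).
#' @param dt Sampling interval in seconds, 1 or 60.
#' @param values Numeric vector of nonnegative movement magnitudes; `NA`
#'   marks missing samples.
#' @param schedule A [light_schedule()]; used to tag every sample with its
#'   lighting phase.
#' @param genotype,sex,monitor,channel Optional metadata.
#' @return An object of class `activity_trace`.
#' @export
activity_trace <- function(fly_id, t0, dt, values,
                           schedule = light_schedule(),
                           genotype = NA_character_, sex = NA_character_,
                           monitor = NA_character_, channel = NA_integer_) {
  stopifnot(length(fly_id) == 1, inherits(t0, "POSIXct"),
            dt > 0, 60 %% dt == 0 || dt %% 60 == 0, length(values) >= 1)
  values <- as.numeric(values)
  bad <- !is.na(values) & (values < 0 | !is.finite(values))
  if (any(bad))
    stop("movement values must be nonnegative and finite (first offender at sample ",
         which(bad)[1], ")")
  tr <- structure(list(
    fly_id = as.character(fly_id),
    t0 = as.POSIXct(as.numeric(t0), origin = "1970-01-01", tz = "UTC"),
    dt = as.numeric(dt),
    values = values,
    schedule = schedule,
    regime = schedule_phase(schedule, t0 + (seq_along(values) - 1) * dt),
    genotype = genotype, sex = sex, monitor = monitor, channel = channel
  ), class = "activity_trace")
  tr
}

#' Sample times of a trace
#' @param trace An `activity_trace`.
#' @return POSIXct vector, one entry per sample (bin start).
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1) * trace$dt
}

#' End of the last sample bin of a trace
#' @param trace An `activity_trace`.
#' @export
trace_end <- function(trace) {
  trace$t0 + length(trace$values) * trace$dt
}

#' @export
print.activity_trace <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<activity_trace> fly %s: %d samples @ %gs (%.2f days) from %s\n",
              x$fly_id, n, x$dt, n * x$dt / 86400,
              format(x$t0, "%Y-%m-%d %H:%M")))
  cat(sprintf("  genotype %s | missing %d samples (%.1f%%)\n",
              x$genotype, sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Restrict a trace to a time window
#'
#' @param trace An `activity_trace`.
#' @param from,to POSIXct window (samples with bin start in `[from, to)`).
#' @return A shorter `activity_trace`.
#' @export
trace_window <- function(trace, from, to) {
  tt <- trace_times(trace)
  keep <- tt >= from & tt < to
  if (!any(keep)) stop("window contains no samples")
  idx <- range(which(keep))
  activity_trace(trace$fly_id, tt[idx[1]], trace$dt,
                 trace$values[idx[1]:idx[2]], trace$schedule,
                 trace$genotype, trace$sex, trace$monitor, trace$channel)
}
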