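#' Light schedule for an experiment
#'
#' Describes the lighting regime of a recording: a 12:12 light/dark (LD)
#' entrainment cycle or constant darkness (DD). Zeitgeber time zero (ZT0) is
#' lights-on by convention; in DD the schedule clock still defines subjective
#' day and night windows.
#'
#' @param lights_on Clock time lights come on, `"HH:MM"` (default `"09:00"`).
#' @param lights_off Clock time lights go off, `"HH:MM"` (default `"21:00"`).
#' @param mode `"LD"` or `"DD"`.
#' @return An object of class `light_schedule`.
#' @examples
#' light_schedule()                      # LD 12:12, lights on 09:00-21:00
#' light_schedule(mode = "DD")           # free-running, subjective phases
#' @export
light_schedule <- function(lights_on = "09:00", lights_off = "21:00",
                           mode = c("LD", "DD")) {
  mode <- match.arg(mode)
  on_s <- parse_clock(lights_on)
  off_s <- parse_clock(lights_off)
  if (mode == "LD" && on_s == off_s)
    stop("in LD mode lights_on and lights_off must differ")
  structure(list(lights_on = on_s, lights_off = off_s, mode = mode),
            class = "light_schedule")
}

# clock string "HH:MM" or "HH:MM:SS" -> seconds after midnight
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(parts) < 2 || length(parts) > 3 || anyNA(parts))
    stop("clock time must be 'HH:MM' or 'HH:MM:SS', got: ", x)
  sum(parts * c(3600, 60, 1)[seq_along(parts)])
}

#' @export
print.light_schedule <- function(x, ...) {
  fmt <- function(s) sprintf("%02d:%02d", s %/% 3600, (s %% 3600) %/% 60)
  cat(sprintf("<light_schedule> %s, lights on %s - off %s (ZT0 = lights-on)\n",
              x$mode, fmt(x$lights_on), fmt(x$lights_off)))
  invisible(x)
}

# seconds after midnight for a vector of POSIXct (timezone-free arithmetic:
# everything in the package lives in UTC)
clock_seconds <- function(t) {
  as.numeric(t) %% 86400
}

# lighting phase of each time point under a schedule: "L" or "D".
# In DD everything is dark; subjective phase is still available through
# phase_windows().
schedule_phase <- function(schedule, t) {
  if (schedule$mode == "DD") return(rep("D", length(t)))
  cs <- clock_seconds(t)
  on <- schedule$lights_on; off <- schedule$lights_off
  lit <- if (on < off) cs >= on & cs < off else cs >= on | cs < off
  ifelse(lit, "L", "D")
}

#' Day/night analysis windows under a schedule
#'
#' Partitions a time span into consecutive 12-h (or schedule-defined) day and
#' night windows. In DD the same clock is used and windows are labelled
#' subjective day / subjective night.
#'
#' @param schedule A [light_schedule()].
#' @param from,to POSIXct span to partition. Windows are clipped to the span.
#' @return A data.frame with columns `start`, `end`, `phase`
#'   (`"day"`/`"night"`) and `cycle` (1-based day index).
#' @export
phase_windows <- function(schedule, from, to) {
  stopifnot(inherits(from, "POSIXct"), inherits(to, "POSIXct"), to > from)
  on <- schedule$lights_on
  # first lights-on at or before `from`
  day0 <- as.POSIXct(floor(as.numeric(from) / 86400) * 86400,
                     origin = "1970-01-01", tz = "UTC")
  anchor <- day0 + on
  if (anchor > from) anchor <- anchor - 86400
  starts <- seq(anchor, to, by = 86400)
  day_len <- (schedule$lights_off - schedule$lights_on) %% 86400
  out <- do.call(rbind, lapply(seq_along(starts), function(i) {
    s <- starts[i]
    data.frame(start = c(s, s + day_len),
               end = c(s + day_len, s + 86400),
               phase = c("day", "night"),
               cycle = i)
  }))
  out$start <- pmax(out$start, from)
  out$end <- pmin(out$end, to)
  out <- out[out$end > out$start, , drop = FALSE]
  rownames(out) <- NULL
  out
}
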