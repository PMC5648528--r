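#' Score sleep bouts by the 5-minute immobility rule
#'
#' Sleep in the fly is defined operationally as any period of no detectable
#' movement lasting at least `min_bout` minutes (5 by default). A sample is
#' immobile iff its movement value is exactly 0 — all sensitivity to what
#' counts as "detectable" lives upstream in the position-to-movement
#' threshold. Every maximal run of consecutive immobile samples whose span
#' reaches `min_bout` becomes exactly one bout; shorter runs contribute no
#' sleep. Missing samples break runs. Runs truncated by the edge of the
#' recording are scored on their observed span.
#'
#' @param trace An [activity_trace()].
#' @param min_bout Minimum bout duration in minutes (> 0).
#' @return An object of class `sleep_bouts`: a data.frame with one row per
#'   bout (`onset` POSIXct, `duration_min`, `phase_at_onset`) carrying the
#'   source trace geometry as attributes (`fly_id`, `t0`, `dt`, `n_samples`,
#'   `min_bout`).
#' @examples
#' sched <- light_schedule()
#' tr <- activity_trace("f1", as.POSIXct("2024-01-01 09:00", tz = "UTC"), 60,
#'                      c(rep(0, 10), 3, rep(0, 7)), sched)
#' detect_sleep_bouts(tr)   # two bouts: 10 min and 7 min
#' @export
detect_sleep_bouts <- function(trace, min_bout = 5) {
  stopifnot(inherits(trace, "activity_trace"), min_bout > 0)
  v <- trace$values
  if (length(v) == 0) stop("empty trace")
  # 0 = immobile, 1 = moving, 2 = missing
  code <- ifelse(is.na(v), 2L, ifelse(v == 0, 0L, 1L))
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 0L & r$lengths * trace$dt >= min_bout * 60
  onset_idx <- starts[keep]
  durs <- r$lengths[keep] * trace$dt / 60
  onsets <- trace$t0 + (onset_idx - 1) * trace$dt
  bouts <- data.frame(
    onset = as.POSIXct(if (length(onset_idx)) onsets else numeric(0),
                       origin = "1970-01-01", tz = "UTC"),
    duration_min = durs,
    phase_at_onset = if (length(onset_idx)) trace$regime[onset_idx]
                     else character(0),
    stringsAsFactors = FALSE
  )
  structure(bouts, class = c("sleep_bouts", "data.frame"),
            fly_id = trace$fly_id, t0 = trace$t0, dt = trace$dt,
            n_samples = length(v), min_bout = min_bout,
            n_missing = sum(code == 2L))
}

#' Binary sleep raster from a bout series
#'
#' Expands bouts back into a per-sample indicator on the source trace's
#' sampling grid (or a coarser/finer one): 1 exactly inside bouts, 0
#' elsewhere. At a bin width coarser than the native grid the value is the
#' fraction of the bin spent asleep, so `sum(raster) * dt` always equals
#' total bout time.
#'
#' @param bouts A [detect_sleep_bouts()] result.
#' @param dt Output bin width in seconds; defaults to the source trace's.
#' @return Numeric vector over the trace span; attribute `t0` and `dt`.
#' @export
sleep_raster <- function(bouts, dt = NULL) {
  stopifnot(inherits(bouts, "sleep_bouts"))
  src_dt <- attr(bouts, "dt")
  n <- attr(bouts, "n_samples")
  if (is.null(dt)) dt <- src_dt
  if (!(dt %% src_dt == 0 || src_dt %% dt == 0))
    stop("raster dt must divide the trace dt or be a multiple of it")
  t0 <- as.numeric(attr(bouts, "t0"))
  span <- n * src_dt
  nb <- ceiling(span / dt)
  out <- numeric(nb)
  if (nrow(bouts) > 0) {
    b0 <- as.numeric(bouts$onset) - t0
    b1 <- b0 + bouts$duration_min * 60
    edges <- seq(0, by = dt, length.out = nb + 1)
    for (k in seq_along(b0)) {
      ov <- pmin(edges[-1], b1[k]) - pmax(edges[-(nb + 1)], b0[k])
      out <- out + pmax(ov, 0) / dt
    }
  }
  structure(out, t0 = attr(bouts, "t0"), dt = dt)
}

#' @export
print.sleep_bouts <- function(x, ...) {
  cat(sprintf("<sleep_bouts> fly %s: %d bouts, %.1f min total (min_bout = %g min)\n",
              attr(x, "fly_id"), nrow(x), sum(x$duration_min),
              attr(x, "min_bout")))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Export a bout table as CSV
#'
#' Writes `fly_id`, ISO-8601 `onset`, `duration_min` and `phase_at_onset`,
#' the interchange format for downstream statistics.
#'
#' @param bouts A `sleep_bouts` object or list of them.
#' @param path Output CSV path.
#' @export
write_bout_table <- function(bouts, path) {
  if (inherits(bouts, "sleep_bouts")) bouts <- list(bouts)
  df <- do.call(rbind, lapply(bouts, function(b) {
    data.frame(fly_id = attr(b, "fly_id"),
               onset = format(b$onset, "%Y-%m-%dT%H:%M:%S"),
               duration_min = b$duration_min,
               phase_at_onset = b$phase_at_onset)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
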