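#' Per-second fly position trace from a video tracker
#'
#' Holds the (x, y) centroid of one fly inside its tube region of interest,
#' sampled once per second, as produced by video tracking. Missing samples
#' (tracking dropouts) are explicit `NA` rows, never silent gaps.
#'
#' @param fly_id Character identifier.
#' @param t0 POSIXct time of the first sample.
#' @param xy Two-column numeric matrix of positions in mm; `NA` rows mark
#'   missing samples.
#' @param roi Numeric `c(xmin, ymin, xmax, ymax)` tube bounding box in mm.
#' @return An object of class `position_trace` (`dt` is fixed at 1 s).
#' @export
position_trace <- function(fly_id, t0, xy, roi = c(0, 0, 65, 5)) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 1, length(roi) == 4)
  ok <- stats::complete.cases(xy)
  inside <- xy[ok, 1] >= roi[1] & xy[ok, 1] <= roi[3] &
    xy[ok, 2] >= roi[2] & xy[ok, 2] <= roi[4]
  if (!all(inside))
    stop("positions fall outside the tube ROI (first at observed sample ",
         which(!inside)[1], ")")
  structure(list(fly_id = as.character(fly_id),
                 t0 = as.POSIXct(as.numeric(t0), origin = "1970-01-01",
                                 tz = "UTC"),
                 dt = 1, xy = xy, roi = roi),
            class = "position_trace")
}

#' Read a position-trace CSV
#'
#' Expects a header `fly_id,t,x,y` with `t` in ISO-8601; one file holds one
#' fly. Missing samples may be encoded as empty/NA x,y fields.
#'
#' @param path CSV path.
#' @param roi Tube bounding box passed to [position_trace()].
#' @return A `position_trace`.
#' @export
read_position_trace <- function(path, roi = c(0, 0, 65, 5)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fly_id", "t", "x", "y")
  if (!all(need %in% names(df)))
    stop("position CSV must have columns fly_id,t,x,y")
  t <- as.POSIXct(sub("T", " ", df$t, fixed = TRUE), tz = "UTC")
  if (any(diff(as.numeric(t)) != 1))
    stop("position trace must be a gapless 1-s series (encode dropouts as NA rows)")
  position_trace(df$fly_id[1], t[1], cbind(df$x, df$y), roi)
}

#' Write a position trace as CSV
#' @param p A `position_trace`.
#' @param path Output path.
#' @export
write_position_trace <- function(p, path) {
  t <- p$t0 + seq_len(nrow(p$xy)) - 1
  utils::write.csv(data.frame(fly_id = p$fly_id,
                              t = format(t, "%Y-%m-%dT%H:%M:%S"),
                              x = p$xy[, 1], y = p$xy[, 2]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert positions to a binned movement series
#'
#' Computes the per-second Euclidean step length, zeroes steps below the
#' detectability threshold `epsilon` (steps smaller than the tracker can
#' resolve count as "no detectable movement"), and sums the surviving
#' distances into bins. Seconds adjacent to a missing position yield missing
#' steps, and any bin containing a missing step is marked missing.
#'
#' @param p A [position_trace()].
#' @param epsilon Detectability threshold in mm per second (default 1.0).
#' @param bin Output bin width in seconds; must divide 60 or be a multiple
#'   of 60 that divides the trace length.
#' @param schedule A [light_schedule()] for the output trace.
#' @param ... Metadata passed to [activity_trace()].
#' @return An [activity_trace()] with `dt = bin` and distance-per-bin values.
#' @export
movement_from_positions <- function(p, epsilon = 1.0, bin = 60,
                                    schedule = light_schedule(), ...) {
  stopifnot(inherits(p, "position_trace"), epsilon >= 0, bin >= 1)
  if (!(60 %% bin == 0 || bin %% 60 == 0))
    stop("bin must divide 60 s or be a multiple of it")
  step <- sqrt(rowSums(diff(p$xy)^2))          # mm per second
  step[!is.na(step) & step < epsilon] <- 0
  # first second of the trace has no predecessor: treat as zero movement
  step <- c(0, step)
  nb <- floor(length(step) / bin)
  if (nb < 1) stop("trace shorter than one bin")
  m <- matrix(step[seq_len(nb * bin)], nrow = bin)
  vals <- colSums(m)                            # NA propagates to the bin
  activity_trace(p$fly_id, p$t0, bin, ifelse(is.na(vals), NA_real_, vals),
                 schedule = schedule, ...)
}
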