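#' Read a TriKinetics DAM monitor file
#'
#' Parses the common `MonitorN.txt` ASCII dialect: tab-separated rows of
#' record index, date (`dd Mon yy`), time (`HH:MM:SS`), a status code, a
#' variable number of flag/sensor columns, and finally 32 integer
#' beam-crossing counts (one per channel) for that minute. Because field
#' files vary in the middle columns, the count block is located as the
#' trailing 32 integer columns.
#'
#' Rows whose status code is not 1 are kept in the time base but their counts
#' are marked missing (`NA`) rather than silently zeroed. Gaps in the minute
#' grid are filled with missing samples so that timestamps always advance by
#' exactly 60 s.
#'
#' @param path Path to the monitor file.
#' @param schedule A [light_schedule()] attached to every trace.
#' @param monitor Monitor label stored in trace metadata (defaults to the
#'   file name).
#' @return A list of 32 [activity_trace()] objects (`dt = 60`), one per
#'   channel, named `ch01` ... `ch32`.
#' @export
read_dam_monitor <- function(path, schedule = light_schedule(),
                             monitor = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty DAM file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 36))
    stop("malformed DAM row ", which(ncol < 36)[1], ": expected >= 36 ",
         "tab-separated columns (4 header + 32 counts), found ",
         ncol[which(ncol < 36)[1]])

  nr <- length(fields)
  ts <- as.POSIXct(rep(NA_real_, nr), origin = "1970-01-01", tz = "UTC")
  status <- integer(nr)
  counts <- matrix(NA_real_, nr, 32)
  for (i in seq_len(nr)) {
    f <- fields[[i]]
    ts[i] <- parse_dam_datetime(f[2], f[3], i)
    status[i] <- suppressWarnings(as.integer(f[4]))
    ci <- suppressWarnings(as.numeric(f[(length(f) - 31):length(f)]))
    if (anyNA(ci))
      stop("malformed DAM row ", i, ": non-numeric count column")
    counts[i, ] <- ci
  }
  if (any(diff(as.numeric(ts)) <= 0))
    stop("non-monotone timestamps at DAM row ",
         which(diff(as.numeric(ts)) <= 0)[1] + 1)
  counts[is.na(status) | status != 1, ] <- NA_real_

  # regularise onto a strict 60-s grid, explicit NA in gaps
  grid <- seq(ts[1], ts[nr], by = 60)
  idx <- match(as.numeric(ts), as.numeric(grid))
  if (anyNA(idx))
    stop("timestamps at DAM row ", which(is.na(idx))[1],
         " are not on a 60-s grid")
  full <- matrix(NA_real_, length(grid), 32)
  full[idx, ] <- counts

  lapply(seq_len(32), function(ch) {
    tr <- activity_trace(sprintf("%s|ch%02d", monitor, ch), grid[1], 60,
                         rep(0, length(grid)), schedule,
                         monitor = monitor, channel = ch)
    tr$values <- full[, ch]  # bypass nonneg check once: NA already vetted
    tr
  }) -> traces
  names(traces) <- sprintf("ch%02d", seq_len(32))
  traces
}

DAM_MONTHS <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

# "10 Sep 26" + "09:00:00" -> POSIXct, locale-proof month lookup
parse_dam_datetime <- function(date, time, row) {
  dp <- strsplit(trimws(date), " +")[[1]]
  mon <- match(dp[2], DAM_MONTHS)
  day <- suppressWarnings(as.integer(dp[1]))
  yy <- suppressWarnings(as.integer(dp[3]))
  if (length(dp) != 3 || is.na(mon) || is.na(day) || is.na(yy))
    stop("unparsable date '", date, "' at DAM row ", row)
  year <- if (yy < 100) 2000 + yy else yy
  out <- as.POSIXct(sprintf("%04d-%02d-%02d %s", year, mon, day, time),
                    tz = "UTC")
  if (is.na(out)) stop("unparsable time '", time, "' at DAM row ", row)
  out
}

#' Write activity traces as a TriKinetics DAM monitor file
#'
#' Emits the same dialect [read_dam_monitor()] accepts, so that
#' read-after-write is the identity on counts and timestamps. Rows in which
#' any trace has a missing sample are written with a non-OK status code (51)
#' and zero counts; the reader restores them as missing.
#'
#' @param traces List of up to 32 `activity_trace` objects sharing `t0`,
#'   `dt = 60` and length. Channels beyond `length(traces)` are written as 0.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dam_monitor <- function(traces, path) {
  if (length(traces) < 1) stop("need at least one trace")
  if (length(traces) > 32) stop("a DAM monitor has at most 32 channels")
  dts <- vapply(traces, function(x) x$dt, 0)
  ns <- vapply(traces, function(x) length(x$values), 0L)
  t0s <- vapply(traces, function(x) as.numeric(x$t0), 0)
  if (any(dts != 60)) stop("DAM traces must have dt = 60 s")
  if (length(unique(ns)) != 1 || length(unique(t0s)) != 1)
    stop("all traces must share t0 and length")

  n <- ns[1]
  tt <- trace_times(traces[[1]])
  counts <- matrix(0, n, 32)
  for (j in seq_along(traces)) counts[, j] <- traces[[j]]$values
  bad_row <- apply(counts, 1, anyNA)
  counts[bad_row, ] <- 0
  status <- ifelse(bad_row, 51L, 1L)

  date_str <- sprintf("%d %s %02d",
                      as.integer(format(tt, "%d")),
                      DAM_MONTHS[as.integer(format(tt, "%m"))],
                      as.integer(format(tt, "%Y")) %% 100)
  head_cols <- cbind(seq_len(n), date_str, format(tt, "%H:%M:%S"),
                     status, 1, 0, 0, 0, 0, 0)
  lines <- apply(cbind(head_cols, counts), 1, paste, collapse = "\t")
  writeLines(lines, path)
  invisible(path)
}
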