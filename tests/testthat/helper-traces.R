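# shared fixtures and independent oracles, built in code

SCHED <- light_schedule()
T0 <- as.POSIXct("2024-01-01 09:00:00", tz = "UTC")  # lights-on

# minute-resolution trace from a numeric vector (NA = missing)
min_trace <- function(values, t0 = T0, schedule = SCHED, ...) {
  activity_trace("test", t0, 60, values, schedule, ...)
}

sec_trace <- function(values, t0 = T0, schedule = SCHED, ...) {
  activity_trace("test", t0, 1, values, schedule, ...)
}

# independent brute-force oracle for bout detection: linear scan over the
# immobility series, no rle, counting maximal zero-runs by span
scan_bouts <- function(values, dt, min_bout = 5) {
  n <- length(values)
  out <- list()
  i <- 1
  while (i <= n) {
    if (!is.na(values[i]) && values[i] == 0) {
      j <- i
      while (j < n && !is.na(values[j + 1]) && values[j + 1] == 0) j <- j + 1
      if ((j - i + 1) * dt >= min_bout * 60)
        out[[length(out) + 1]] <- c(start = i, len = j - i + 1)
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# minutes of overlap of bout rows with [from, to) computed independently
oracle_overlap <- function(bouts, from, to) {
  tot <- 0
  for (k in seq_len(nrow(bouts))) {
    a <- as.numeric(bouts$onset[k])
    b <- a + bouts$duration_min[k] * 60
    tot <- tot + max(0, min(b, as.numeric(to)) - max(a, as.numeric(from)))
  }
  tot / 60
}
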