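#' Chi-square (Sokolove-Bushell) periodogram
#'
#' Estimates the free-running period of a locomotor series recorded in
#' constant darkness. For each candidate period P (in samples) the series is
#' folded into K complete cycles of P columns and the statistic
#'
#'   Q(P) = K * N * sum_h (M_h - M)^2 / sum_i (x_i - M)^2
#'
#' is computed, where M_h are the P column means over the K cycles, M is the
#' grand mean and N = K * P the number of samples used. Under the null of no
#' rhythm Q(P) is approximately chi-square with P - 1 degrees of freedom,
#' which provides the per-period significance line. The best period is the
#' candidate with maximal Q among those exceeding the line; a trace with no
#' supra-threshold candidate (or no variance at all) is flagged arrhythmic.
#'
#' Non-integer candidate periods are rounded to the nearest whole sample for
#' folding; the reported period is the candidate value on the search grid.
#'
#' @param trace An [activity_trace()] of per-minute data covering at least
#'   two full cycles of the longest candidate period (>= 3 days advised).
#' @param p_min,p_max Period search range in hours (default 18-30).
#' @param step Grid step in hours (default 0.1).
#' @param alpha Significance level for the chi-square line (default 0.05).
#' @return An object of class `periodogram`: data.frame with `period_h`,
#'   `Q`, `threshold`, `significant`; attributes `best_period` (hours, NA if
#'   arrhythmic), `arrhythmic`, `alpha`, `fly_id`.
#' @examples
#' sched <- light_schedule(mode = "DD")
#' x <- rep(c(rep(8, 720), rep(0, 720)), 6)   # square wave, 24-h period
#' tr <- activity_trace("f", as.POSIXct("2024-01-01", tz = "UTC"), 60, x, sched)
#' attr(chi_square_periodogram(tr), "best_period")   # 24
#' @export
chi_square_periodogram <- function(trace, p_min = 18, p_max = 30,
                                   step = 0.1, alpha = 0.05) {
  stopifnot(inherits(trace, "activity_trace"), p_min > 0, p_max > p_min)
  x <- trace$values
  x <- x[!is.na(x)]
  n_total <- length(x)
  p_max_samp <- round(p_max * 3600 / trace$dt)
  if (n_total < 2 * p_max_samp)
    stop("trace too short: need at least 2 complete cycles at p_max (",
         2 * p_max_samp, " samples), have ", n_total)
  periods_h <- seq(p_min, p_max, by = step)
  res <- vapply(periods_h, function(ph) {
    P <- round(ph * 3600 / trace$dt)
    K <- floor(n_total / P)
    xs <- x[seq_len(K * P)]
    M <- mean(xs)
    ss_tot <- sum((xs - M)^2)
    if (ss_tot == 0) return(c(NA_real_, NA_real_))
    Mh <- rowMeans(matrix(xs, nrow = P))
    Q <- K * (K * P) * sum((Mh - M)^2) / ss_tot
    c(Q, stats::qchisq(1 - alpha, df = P - 1))
  }, numeric(2))
  df <- data.frame(period_h = periods_h, Q = res[1, ], threshold = res[2, ])
  df$significant <- !is.na(df$Q) & df$Q > df$threshold
  arrhythmic <- all(is.na(df$Q)) || !any(df$significant)
  best <- if (arrhythmic) NA_real_
          else df$period_h[which.max(ifelse(df$significant, df$Q, -Inf))]
  structure(df, class = c("periodogram", "data.frame"),
            best_period = best, arrhythmic = arrhythmic, alpha = alpha,
            fly_id = trace$fly_id)
}

#' @export
print.periodogram <- function(x, ...) {
  if (attr(x, "arrhythmic"))
    cat(sprintf("<periodogram> fly %s: arrhythmic (no period above the %g line)\n",
                attr(x, "fly_id"), attr(x, "alpha")))
  else
    cat(sprintf("<periodogram> fly %s: best period %.1f h (alpha = %g)\n",
                attr(x, "fly_id"), attr(x, "best_period"), attr(x, "alpha")))
  invisible(x)
}

#' Free-running periods for a cohort
#'
#' Runs [chi_square_periodogram()] on every fly and summarises: per-fly
#' period table with arrhythmic flags, and mean +/- SEM over rhythmic flies.
#'
#' @param traces List of [activity_trace()].
#' @param ... Passed to [chi_square_periodogram()].
#' @return List: `flies` (data.frame `fly_id`, `period_h`, `arrhythmic`),
#'   `mean_h`, `sem_h`, `n_rhythmic`, `n_arrhythmic`.
#' @export
cohort_periods <- function(traces, ...) {
  rows <- lapply(traces, function(tr) {
    pg <- chi_square_periodogram(tr, ...)
    data.frame(fly_id = tr$fly_id, period_h = attr(pg, "best_period"),
               arrhythmic = attr(pg, "arrhythmic"),
               stringsAsFactors = FALSE)
  })
  flies <- do.call(rbind, rows)
  per <- flies$period_h[!flies$arrhythmic]
  list(flies = flies,
       mean_h = if (length(per)) mean(per) else NA_real_,
       sem_h = if (length(per) > 1) stats::sd(per) / sqrt(length(per))
               else NA_real_,
       n_rhythmic = length(per),
       n_arrhythmic = sum(flies$arrhythmic))
}
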