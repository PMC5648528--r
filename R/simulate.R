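# Synthetic fly activity: a per-minute two-state (wake/sleep) inhomogeneous
# Markov chain driven by a sinusoidal circadian input C(t) and a homeostatic
# pressure variable H that charges while awake and discharges during sleep
# (a two-process-style model). Awake minutes emit Poisson beam counts,
# asleep minutes emit zero. This is the minimal generative model that
# exhibits both phenotype axes the analyses separate: total sleep amount
# (baseline transition logits) and sleep homeostasis (pressure weights),
# which can be knocked out independently via genotype multipliers.

#' Simulation parameters for the wake/sleep generator
#'
#' Per-minute transition probabilities are logistic in a circadian drive
#' C(t) = cos(2*pi*(t - phi)/tau) (t in hours since lights-on) and the
#' homeostatic pressure H in (0, 1):
#'
#'   P(wake -> sleep) = logistic(a0 + a_c * C + a_h * H)
#'   P(sleep -> wake) = logistic(b0 - b_c * C - b_h * H)
#'
#' While awake H charges as H <- H + (1 - H) * dt / tau_w; during sleep it
#' discharges as H <- H * exp(-dt / tau_s) (dt = 1 minute in hours).
#'
#' Defaults are calibrated so a wild-type cohort reproduces the canonical
#' fly phenomenology: consolidated night sleep exceeding day sleep under LD
#' 12:12, and, after a fully effective overnight mechanical deprivation,
#' recovery of roughly all lost sleep within 24 h.
#'
#' @param tau Circadian period, hours (default 24).
#' @param phi Phase of peak sleep drive, hours after lights-on (default 18,
#'   i.e. mid-night).
#' @param a0,a_c,a_h Wake-to-sleep logit: baseline, circadian weight,
#'   homeostatic weight.
#' @param b0,b_c,b_h Sleep-to-wake logit: baseline, circadian weight,
#'   homeostatic weight.
#' @param tau_w,tau_s Homeostat charge / discharge time constants, hours.
#' @param h0 Initial homeostatic pressure; the default is the stationary
#'   mean under the wild-type defaults, so recordings start equilibrated
#'   and baseline length does not bias rebound estimates.
#' @param lambda_wake Mean beam counts per waking minute (Poisson) away
#'   from the evening peak.
#' @param lambda_stim Extra mean counts during mechanical-stimulation
#'   minutes (the shaker itself drives beam crossings).
#' @param evening_peak Amplitude of the evening activity peak: waking
#'   counts are inflated up to `(1 + evening_peak)`-fold in a sharp bump
#'   centred at subjective dusk (6 h before the sleep-drive peak), the
#'   classic crepuscular locomotor surge that dominates fly actograms.
#' @param evening_sharpness Exponent shaping the bump width (a
#'   `cos^evening_sharpness` window; 16 gives roughly a +/- 1.5 h peak).
#' @param n_flies,days Cohort size and recording length.
#' @param seed Master seed; all randomness derives from it.
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(tau = 24, phi = 18,
                       a0 = -11.2, a_c = 1.5, a_h = 10.5,
                       b0 = -1.0, b_c = 0.3, b_h = 18,
                       tau_w = 38, tau_s = 16,
                       lambda_wake = 2, lambda_stim = 5,
                       evening_peak = 8, evening_sharpness = 16,
                       h0 = 0.36, n_flies = 48, days = 4,
                       seed = 1L) {
  p <- list(tau = tau, phi = phi, a0 = a0, a_c = a_c, a_h = a_h,
            b0 = b0, b_c = b_c, b_h = b_h, tau_w = tau_w, tau_s = tau_s,
            lambda_wake = lambda_wake, lambda_stim = lambda_stim,
            evening_peak = evening_peak,
            evening_sharpness = evening_sharpness, h0 = h0,
            n_flies = n_flies, days = days, seed = as.integer(seed))
  if (!(tau > 0 && tau_w > 0 && tau_s > 0 && lambda_wake > 0))
    stop("tau, tau_w, tau_s and lambda_wake must be positive")
  if (evening_peak < 0 || evening_sharpness < 1)
    stop("evening_peak must be >= 0 and evening_sharpness >= 1")
  num <- vapply(p, is.numeric, TRUE)
  if (!all(num) || any(!vapply(p[num], function(v) all(is.finite(v)), TRUE)))
    stop("all parameters must be finite numbers")
  structure(p, class = "sim_params")
}

#' Genotype specification for the generator
#'
#' Maps a phenotype onto multiplicative knobs on the wild-type parameters:
#' `m_a0` scales the wake-to-sleep baseline (values > 1 make the negative
#' logit more negative, i.e. less sleep), `m_ah`/`m_bh` scale the
#' homeostatic weights (0 disables rebound), `m_b0` scales the
#' sleep-to-wake baseline.
#'
#' Presets: `"wt"` (all 1); `"low_sleep"` (homeostatic gain halved, which
#' under these dynamics lowers total sleep while leaving rebound intact)
#' modelling short-sleeping mutants with normal recovery;
#' `"homeostat_half"` (halved gain with baseline compensation, an
#' intermediate point on the homeostat axis); `"homeostat_null"` (pressure
#' decoupled from behaviour, baselines compensated so the fly still
#' sleeps) modelling mutants with diminished sleep rebound. Because the
#' pressure feedback defends baseline sleep, cutting the homeostatic gain
#' -- not the sleep-drive intercept -- is what yields a stable low-sleep
#' phenotype here; the null keeps moderate sleep only because its
#' intercepts are recalibrated.
#'
#' @param label Genotype label.
#' @param m_a0,m_ah,m_b0,m_bh Multipliers (> 0, except `m_ah`/`m_bh` which
#'   may be 0).
#' @return An object of class `genotype_spec`.
#' @export
genotype_spec <- function(label, m_a0 = 1, m_ah = 1, m_b0 = 1, m_bh = m_ah) {
  if (m_a0 <= 0 || m_b0 <= 0 || m_ah < 0 || m_bh < 0)
    stop("multipliers must be positive (m_ah/m_bh may be 0)")
  structure(list(label = label, m_a0 = m_a0, m_ah = m_ah,
                 m_b0 = m_b0, m_bh = m_bh),
            class = "genotype_spec")
}

#' @rdname genotype_spec
#' @param name Preset name: `"wt"`, `"low_sleep"`, `"homeostat_half"` or
#'   `"homeostat_null"`.
#' @export
genotype_preset <- function(name = c("wt", "low_sleep", "homeostat_half",
                                     "homeostat_null")) {
  name <- match.arg(name)
  switch(name,
         wt = genotype_spec("wt"),
         low_sleep = genotype_spec("low_sleep", m_ah = 0.7),
         homeostat_half = genotype_spec("homeostat_half", m_a0 = 0.63,
                                        m_ah = 0.5, m_b0 = 2.0),
         homeostat_null = genotype_spec("homeostat_null", m_a0 = 0.41,
                                        m_ah = 0, m_b0 = 2.3))
}

# stimulation minutes (forced wake) for a deprivation design on a minute
# grid starting at t0
stim_minutes <- function(protocol, t0, n_min) {
  stim <- logical(n_min)
  if (is.null(protocol)) return(stim)
  m0 <- as.numeric(t0)
  e0 <- as.numeric(protocol$epochs$start)
  e1 <- as.numeric(protocol$epochs$end)
  for (k in seq_along(e0)) {
    i0 <- floor((e0[k] - m0) / 60) + 1
    i1 <- ceiling((e1[k] - m0) / 60)
    i0 <- max(i0, 1); i1 <- min(i1, n_min)
    if (i0 <= i1) stim[i0:i1] <- TRUE
  }
  stim
}

#' Simulate one fly
#'
#' Runs the two-state chain minute by minute and emits a DAM-style activity
#' trace together with the latent sleep state and pressure series (the
#' ground truth the scoring pipeline can be checked against). During
#' stimulation minutes of a deprivation protocol the state is forced to
#' wake and sleep entry is blocked.
#'
#' @param params A [sim_params()].
#' @param genotype A [genotype_spec()] (default wild type).
#' @param schedule A [light_schedule()].
#' @param protocol Optional [deprivation_design()].
#' @param seed Per-fly seed (default `params$seed`).
#' @param fly_id Identifier for the trace.
#' @param t0 POSIXct first sample; defaults to lights-on on 2024-01-01.
#' @return An object of class `sim_fly`: list with `trace`
#'   ([activity_trace()]), `asleep` (logical per minute, latent state),
#'   `pressure` (H per minute), `stim` (forced-wake minutes).
#' @export
simulate_fly <- function(params, genotype = genotype_preset("wt"),
                         schedule = light_schedule(), protocol = NULL,
                         seed = params$seed, fly_id = "sim1", t0 = NULL) {
  stopifnot(inherits(params, "sim_params"), inherits(genotype, "genotype_spec"))
  if (is.null(t0))
    t0 <- as.POSIXct("2024-01-01", tz = "UTC") + schedule$lights_on
  n <- params$days * 1440
  a0 <- params$a0 * genotype$m_a0
  a_h <- params$a_h * genotype$m_ah
  b0 <- params$b0 * genotype$m_b0
  b_h <- params$b_h * genotype$m_bh
  hrs <- (seq_len(n) - 1) / 60
  C <- cos(2 * pi * (hrs - params$phi) / params$tau)
  stim <- stim_minutes(protocol, t0, n)
  dt_h <- 1 / 60

  set.seed(seed)
  u <- stats::runif(n)
  asleep <- logical(n)
  H <- numeric(n)
  h <- params$h0; s <- FALSE
  for (i in seq_len(n)) {
    if (stim[i]) {
      s <- FALSE                      # forced wake; sleep entry blocked
    } else if (s) {
      if (u[i] < stats::plogis(b0 - params$b_c * C[i] - b_h * h)) s <- FALSE
    } else {
      if (u[i] < stats::plogis(a0 + params$a_c * C[i] + a_h * h)) s <- TRUE
    }
    h <- if (s) h * exp(-dt_h / params$tau_s)
         else h + (1 - h) * dt_h / params$tau_w
    asleep[i] <- s
    H[i] <- h
  }
  counts <- numeric(n)
  dusk <- cos(2 * pi * (hrs - (params$phi - 6)) / params$tau)
  lam <- params$lambda_wake *
    (1 + params$evening_peak * pmax(0, dusk)^params$evening_sharpness) +
    ifelse(stim, params$lambda_stim, 0)
  counts[!asleep] <- stats::rpois(sum(!asleep), lam[!asleep])
  structure(list(
    trace = activity_trace(fly_id, t0, 60, counts, schedule,
                           genotype = genotype$label),
    asleep = asleep, pressure = H, stim = stim),
    class = "sim_fly")
}

#' Latent sleep minutes of a simulated fly in a window
#' @param sim A [simulate_fly()] result.
#' @param from,to POSIXct window.
#' @return Minutes of latent (ground-truth) sleep state in the window.
#' @export
latent_sleep <- function(sim, from, to) {
  tt <- trace_times(sim$trace)
  sum(sim$asleep[tt >= from & tt < to])
}

#' Simulate a cohort of flies
#'
#' Independent flies with per-fly seeds derived deterministically from the
#' master seed, optionally across several genotypes, plus a ground-truth
#' table of latent sleep per day/night window for oracle checks.
#'
#' @param params A [sim_params()]; `params$n_flies` is used when
#'   `genotypes` does not carry sizes.
#' @param genotypes Named integer vector of group sizes keyed by preset
#'   name (e.g. `c(wt = 48, homeostat_null = 48)`), or a list of
#'   `list(spec = genotype_spec, n = int)`.
#' @param schedule,protocol As in [simulate_fly()].
#' @param t0 POSIXct first sample for every fly.
#' @return An object of class `sim_cohort`: list with `flies` (list of
#'   `sim_fly`), `traces` (their activity traces), `truth` (data.frame
#'   `fly_id`, `genotype`, `phase`, `cycle`, `latent_sleep_min`), `params`.
#' @export
simulate_cohort <- function(params, genotypes = c(wt = params$n_flies),
                            schedule = light_schedule(), protocol = NULL,
                            t0 = NULL) {
  specs <- if (is.list(genotypes)) genotypes
           else lapply(names(genotypes), function(g)
             list(spec = genotype_preset(g), n = genotypes[[g]]))
  total <- sum(vapply(specs, function(s) s$n, 0))
  if (total < 1) stop("cohort must contain at least one fly")
  set.seed(params$seed)
  fly_seeds <- sample.int(.Machine$integer.max - 1, total)
  flies <- vector("list", total)
  i <- 0
  for (sp in specs) {
    for (k in seq_len(sp$n)) {
      i <- i + 1
      flies[[i]] <- simulate_fly(params, sp$spec, schedule, protocol,
                                 seed = fly_seeds[i],
                                 fly_id = sprintf("%s_%02d", sp$spec$label, k),
                                 t0 = t0)
    }
  }
  traces <- lapply(flies, function(f) f$trace)
  tr1 <- traces[[1]]
  pw <- phase_windows(schedule, tr1$t0, trace_end(tr1))
  truth <- do.call(rbind, lapply(flies, function(f)
    data.frame(fly_id = f$trace$fly_id, genotype = f$trace$genotype,
               phase = pw$phase, cycle = pw$cycle,
               latent_sleep_min = vapply(seq_len(nrow(pw)), function(j)
                 latent_sleep(f, pw$start[j], pw$end[j]), 0),
               stringsAsFactors = FALSE)))
  structure(list(flies = flies, traces = traces, truth = truth,
                 params = params),
            class = "sim_cohort")
}

#' Per-second positions for a simulated fly
#'
#' Derives a video-style 1-s position trace from a simulated minute-level
#' fly: each waking minute's k beam counts become k one-second walking
#' steps above the detectability threshold (reflected inside the tube);
#' all other seconds carry sub-threshold jitter, so the minute-level
#' immobility pattern is preserved under [movement_from_positions()].
#'
#' @param sim A [simulate_fly()] result.
#' @param from,to POSIXct window to render (defaults to first hour).
#' @param roi Tube bounding box `c(xmin, ymin, xmax, ymax)` in mm.
#' @param epsilon Detectability threshold the positions are built around.
#' @return A [position_trace()].
#' @export
positions_from_sim <- function(sim, from = sim$trace$t0,
                               to = sim$trace$t0 + 3600,
                               roi = c(0, 0, 65, 5), epsilon = 1.0) {
  tt <- trace_times(sim$trace)
  idx <- which(tt >= from & tt < to)
  if (length(idx) == 0) stop("window outside simulated span")
  nsec <- length(idx) * 60
  x <- numeric(nsec); y <- numeric(nsec)
  cx <- mean(roi[c(1, 3)]); cy <- mean(roi[c(2, 4)])
  pos <- c(cx, cy); dir <- 1
  s <- 0
  for (m in idx) {
    k <- sim$trace$values[m]
    k <- if (is.na(k)) 0 else min(k, 60)
    move_at <- if (k > 0) sample(60, k) else integer(0)
    for (j in seq_len(60)) {
      s <- s + 1
      if (j %in% move_at) {
        step <- stats::runif(1, 1.5 * epsilon, 4)
        pos[1] <- pos[1] + dir * step
        if (pos[1] > roi[3]) { pos[1] <- 2 * roi[3] - pos[1]; dir <- -dir }
        if (pos[1] < roi[1]) { pos[1] <- 2 * roi[1] - pos[1]; dir <- -dir }
      } else {
        pos[2] <- min(max(cy + stats::runif(1, -0.1, 0.1) * epsilon,
                          roi[2]), roi[4])
      }
      x[s] <- pos[1]; y[s] <- pos[2]
    }
  }
  position_trace(sim$trace$fly_id, tt[idx[1]], cbind(x, y), roi)
}
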