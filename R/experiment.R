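# Experiment-level drivers: a single YAML config describes inputs, light
# schedule, analysis parameters, group assignments and (optionally) a
# deprivation design or simulation block; the cmd_* functions tie the
# pipeline stages into the three analyses (sleep scoring, rebound,
# circadian period) plus synthetic-data generation, writing tidy CSVs and
# a run log. A thin Rscript wrapper in inst/scripts/flysleep.R exposes
# them as shell subcommands.

#' Read and validate an experiment config
#'
#' @param path YAML config path. Recognised blocks: `input` (`format`
#'   `"dam"`, `path`), `schedule` (`lights_on`, `lights_off`, `mode`),
#'   `params` (`epsilon`, `min_bout`, `period_range`, `period_step`,
#'   `alpha`), `groups` (genotype label -> channel numbers), `deprivation`
#'   (`start`, `duration_h`, `cycle_s`, `stim_s`, `horizon_h`, `seed`),
#'   `sim` (`n_flies`, `days`, `seed`, `genotypes`).
#' @return The config list with defaults filled and schedule/paths
#'   validated, class `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  sc <- cfg$schedule
  cfg$schedule_obj <- light_schedule(
    lights_on = if (is.null(sc$lights_on)) "09:00" else sc$lights_on,
    lights_off = if (is.null(sc$lights_off)) "21:00" else sc$lights_off,
    mode = if (is.null(sc$mode)) "LD" else sc$mode)
  p <- cfg$params
  cfg$params <- list(
    epsilon = if (is.null(p$epsilon)) 1.0 else p$epsilon,
    min_bout = if (is.null(p$min_bout)) 5 else p$min_bout,
    period_range = if (is.null(p$period_range)) c(18, 30) else p$period_range,
    period_step = if (is.null(p$period_step)) 0.1 else p$period_step,
    alpha = if (is.null(p$alpha)) 0.05 else p$alpha)
  if (!is.null(cfg$input) && !is.null(cfg$input$path)) {
    cfg$input$path <- file.path(dirname(path), cfg$input$path)
    if (!file.exists(cfg$input$path))
      stop("input file not found: ", cfg$input$path)
  }
  structure(cfg, class = c("experiment_config", "list"))
}

load_config_traces <- function(cfg) {
  if (is.null(cfg$input)) stop("config has no input block")
  traces <- read_dam_monitor(cfg$input$path, cfg$schedule_obj)
  if (is.null(cfg$groups)) stop("config has no groups block")
  out <- list()
  for (g in names(cfg$groups)) {
    ch <- cfg$groups[[g]]
    bad <- ch[ch < 1 | ch > length(traces)]
    if (length(bad))
      stop("group '", g, "' references missing channel ", bad[1])
    for (c in ch) {
      tr <- traces[[c]]
      tr$genotype <- g
      out[[length(out) + 1]] <- tr
    }
  }
  out
}

write_run_log <- function(out_dir, cmd, cfg, extra = list()) {
  log <- c(list(command = cmd, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                package_version = as.character(utils::packageVersion("flysleepr")),
                params = cfg$params), extra)
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
}

#' Score sleep and compute per-phase metrics for a configured experiment
#'
#' Runs io -> scoring -> metrics -> group statistics for the configured
#' groups. Writes `bouts.csv`, `metrics.csv`, `profile_<genotype>.csv` and
#' `run_log.yaml` into `out_dir`.
#'
#' @param config Path to a YAML config or an `experiment_config`.
#' @param out_dir Output directory.
#' @return Invisibly, list with `bouts`, `metrics`, `profiles`.
#' @export
cmd_score <- function(config, out_dir) {
  cfg <- if (inherits(config, "experiment_config")) config
         else read_experiment_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traces <- load_config_traces(cfg)
  bouts <- lapply(traces, detect_sleep_bouts, min_bout = cfg$params$min_bout)
  write_bout_table(bouts, file.path(out_dir, "bouts.csv"))
  metrics <- do.call(rbind, lapply(seq_along(traces), function(i) {
    m <- phase_metrics(bouts[[i]], traces[[i]], cfg$schedule_obj)
    m$genotype <- traces[[i]]$genotype
    m
  }))
  mm <- metrics
  mm$start <- format(mm$start, "%Y-%m-%dT%H:%M:%S")
  mm$end <- format(mm$end, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(mm, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  genos <- unique(vapply(traces, function(tr) tr$genotype, ""))
  profiles <- list()
  for (g in genos) {
    sel <- vapply(traces, function(tr) identical(tr$genotype, g), TRUE)
    pr <- sleep_profile(bouts[sel])
    profiles[[g]] <- pr
    pp <- as.data.frame(pr)
    pp$bin_start <- format(pp$bin_start, "%Y-%m-%dT%H:%M:%S")
    utils::write.csv(pp, file.path(out_dir, sprintf("profile_%s.csv", g)),
                     row.names = FALSE, quote = FALSE)
  }
  write_run_log(out_dir, "score", cfg,
                list(n_flies = length(traces), groups = names(cfg$groups)))
  invisible(list(bouts = bouts, metrics = metrics, profiles = profiles))
}

#' Deprivation efficiency and rebound analysis for a configured experiment
#'
#' Writes per-fly `rebound_flies.csv` (efficiency, loss, 24-h recovery,
#' exclusion reasons), the hourly per-fly `rebound_curves.csv`, the group
#' summary `rebound_group.csv`, and a run log. Both loss conventions are
#' emitted (columns `lost_min` for the configured mode and
#' `lost_min_strict` for the baseline-night convention).
#'
#' @param config Path or `experiment_config` with a `deprivation` block
#'   (`start` ISO datetime; optional `duration_h`, `cycle_s`, `stim_s`,
#'   `horizon_h`, `seed`).
#' @param out_dir Output directory.
#' @param loss_mode `"difference"` (default) or `"baseline"`.
#' @return Invisibly, the [rebound_analysis()] result.
#' @export
cmd_rebound <- function(config, out_dir,
                        loss_mode = c("difference", "baseline")) {
  loss_mode <- match.arg(loss_mode)
  cfg <- if (inherits(config, "experiment_config")) config
         else read_experiment_config(config)
  if (is.null(cfg$deprivation))
    stop("config has no deprivation block")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dp <- cfg$deprivation
  if (!is.null(dp$seed)) set.seed(dp$seed)
  design <- deprivation_design(
    as.POSIXct(dp$start, tz = "UTC"),
    duration_h = if (is.null(dp$duration_h)) 12 else dp$duration_h,
    cycle_s = if (is.null(dp$cycle_s)) 180 else dp$cycle_s,
    stim_s = if (is.null(dp$stim_s)) 20 else dp$stim_s,
    horizon_h = if (is.null(dp$horizon_h)) 24 else dp$horizon_h)
  traces <- load_config_traces(cfg)
  res <- rebound_analysis(traces, design, min_bout = cfg$params$min_bout,
                          loss_mode = loss_mode)
  res$flies$lost_min_strict <- res$flies$baseline_night_min
  utils::write.csv(res$flies, file.path(out_dir, "rebound_flies.csv"),
                   row.names = FALSE, quote = FALSE)
  curves <- do.call(rbind, lapply(res$curves, function(cu)
    data.frame(fly_id = attr(cu, "fly_id"), lost_min = attr(cu, "lost_min"),
               h = cu$h, cum_percent = cu$cum_percent)))
  if (!is.null(curves))
    utils::write.csv(curves, file.path(out_dir, "rebound_curves.csv"),
                     row.names = FALSE, quote = FALSE)
  if (!is.null(res$group))
    utils::write.csv(res$group$curve,
                     file.path(out_dir, "rebound_group.csv"),
                     row.names = FALSE, quote = FALSE)
  write_run_log(out_dir, "rebound", cfg,
                list(loss_mode = loss_mode,
                     n_excluded = sum(res$flies$excluded)))
  invisible(res)
}

#' Free-running period analysis for a configured experiment
#'
#' Writes the per-fly period table (`periods.csv`, with arrhythmic flags),
#' one periodogram CSV per fly under `periodograms/`, and a run log.
#'
#' @param config Path or `experiment_config`.
#' @param out_dir Output directory.
#' @return Invisibly, the [cohort_periods()] result.
#' @export
cmd_period <- function(config, out_dir) {
  cfg <- if (inherits(config, "experiment_config")) config
         else read_experiment_config(config)
  dir.create(file.path(out_dir, "periodograms"), showWarnings = FALSE,
             recursive = TRUE)
  traces <- load_config_traces(cfg)
  pr <- cfg$params$period_range
  res <- cohort_periods(traces, p_min = pr[1], p_max = pr[2],
                        step = cfg$params$period_step,
                        alpha = cfg$params$alpha)
  utils::write.csv(res$flies, file.path(out_dir, "periods.csv"),
                   row.names = FALSE, quote = FALSE)
  for (tr in traces) {
    pg <- chi_square_periodogram(tr, p_min = pr[1], p_max = pr[2],
                                 step = cfg$params$period_step,
                                 alpha = cfg$params$alpha)
    utils::write.csv(as.data.frame(pg),
                     file.path(out_dir, "periodograms",
                               paste0(gsub("[^A-Za-z0-9_]", "_",
                                           tr$fly_id), ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  write_run_log(out_dir, "period", cfg,
                list(mean_h = res$mean_h, n_rhythmic = res$n_rhythmic))
  invisible(res)
}

#' Generate a synthetic experiment from a config
#'
#' Simulates the cohort described by the config's `sim` block and writes a
#' DAM monitor file (32 channels max per file), a latent-truth table and a
#' derived config so the other commands can consume the output directly.
#'
#' @param config Path or `experiment_config` with a `sim` block.
#' @param out_dir Output directory.
#' @param seed Optional override of the sim block's seed.
#' @return Invisibly, the [simulate_cohort()] result.
#' @export
cmd_simulate <- function(config, out_dir, seed = NULL) {
  cfg <- if (inherits(config, "experiment_config")) config
         else read_experiment_config(config)
  if (is.null(cfg$sim)) stop("config has no sim block")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sm <- cfg$sim
  params <- sim_params(
    n_flies = if (is.null(sm$n_flies)) 48 else sm$n_flies,
    days = if (is.null(sm$days)) 4 else sm$days,
    seed = if (!is.null(seed)) seed else
      if (is.null(sm$seed)) 1L else sm$seed)
  genotypes <- if (is.null(sm$genotypes)) c(wt = params$n_flies)
               else unlist(sm$genotypes)
  cohort <- simulate_cohort(params, genotypes, cfg$schedule_obj)
  n <- length(cohort$traces)
  if (n > 32) stop("cmd_simulate writes a single monitor: max 32 flies")
  write_dam_monitor(cohort$traces, file.path(out_dir, "Monitor1.txt"))
  utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  groups <- split(seq_len(n),
                  vapply(cohort$traces, function(tr) tr$genotype, ""))
  yaml::write_yaml(list(
    input = list(format = "dam", path = "Monitor1.txt"),
    schedule = cfg$schedule, params = cfg$params[c("epsilon", "min_bout")],
    groups = groups), file.path(out_dir, "experiment.yaml"))
  write_run_log(out_dir, "simulate", cfg, list(seed = params$seed, n = n))
  invisible(cohort)
}
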