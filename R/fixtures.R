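#' Generate the standard fixture set
#'
#' Writes a small deterministic dataset exercising every input format the
#' pipeline reads: a 2-day, 8-fly DAM monitor file from the wild-type
#' generator, a 1-h per-second position trace for one fly, and an
#' experiment config. Regeneration under the same seed is byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed (default 42).
#' @param n_flies,days Cohort geometry (defaults 8 flies, 2 days).
#' @return Named list of written paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 42, n_flies = 8, days = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sched <- light_schedule()
  params <- sim_params(n_flies = n_flies, days = days, seed = seed)
  cohort <- simulate_cohort(params, schedule = sched)

  dam_path <- file.path(out_dir, "Monitor1.txt")
  write_dam_monitor(cohort$traces, dam_path)

  pos_path <- file.path(out_dir, "positions_fly1.csv")
  set.seed(seed + 1L)
  # render an hour of the first night so the trace contains sleep bouts
  night0 <- cohort$traces[[1]]$t0 + 15 * 3600
  pos <- positions_from_sim(cohort$flies[[1]], from = night0,
                            to = night0 + 3600)
  write_position_trace(pos, pos_path)

  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(cohort$truth, truth_path, row.names = FALSE,
                   quote = FALSE)

  cfg_path <- file.path(out_dir, "experiment.yaml")
  cfg <- list(
    input = list(format = "dam", path = "Monitor1.txt"),
    schedule = list(lights_on = "09:00", lights_off = "21:00", mode = "LD"),
    params = list(epsilon = 1.0, min_bout = 5,
                  period_range = c(18, 30), period_step = 0.1,
                  alpha = 0.05),
    groups = list(wt = seq_len(n_flies)),
    sim = list(n_flies = n_flies, days = days, seed = seed,
               genotypes = list(wt = n_flies))
  )
  yaml::write_yaml(cfg, cfg_path)
  invisible(list(dam = dam_path, positions = pos_path, truth = truth_path,
                 config = cfg_path))
}
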