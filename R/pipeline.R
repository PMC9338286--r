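#' Run the full simulate-analyze-population pipeline
#'
#' Executes every stage from one configuration: simulates the experiment
#' (per-cell ground truths over the window-by-level grid), writes the trial
#' table and ground-truth manifest, analyzes each session (five probit
#' models per stimulation group, contrasts, value ranges, summaries), runs
#' the population contrasts per window and parameter, builds the rectified
#' and max-normalized effect table, and writes a run manifest (package
#' version, seed, config hash) so any artifact can be regenerated from
#' config + seed alone.
#'
#' @param config configuration list (see [read_config()]) or path to a JSON
#'   config file.
#' @param out_dir output directory (created if needed).
#' @param seed master seed for the simulation.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `sessions` (wide per-session table),
#'   `effects` (effect table), `population` (per window x parameter test
#'   summaries), and `paths` of all written artifacts.
#' @export
run_pipeline <- function(config, out_dir, seed = 1, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  say("stage 1/4: simulate")
  cells <- config_cells(config)
  sim <- simulate_experiment(cells, design_args = config$design,
                             design_grid = config$design_grid, seed = seed)
  trials_path <- file.path(out_dir, "trials.tsv")
  write_trials(sim$trials, trials_path)
  manifest_path <- file.path(out_dir, "ground_truth_manifest.tsv")
  utils::write.table(sim$manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")

  say("stage 2/4: per-session analysis")
  ids <- unique(sim$trials$session_id)
  results <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tr <- sim$trials[sim$trials$session_id == ids[i], , drop = FALSE]
    results[[i]] <- tryCatch(
      analyze_session(tr, min_trials = config$analysis$min_trials),
      stimchoice_error = function(e) {
        say(sprintf("  session %s failed: %s", ids[i], conditionMessage(e)))
        NULL
      })
  }
  results <- Filter(Negate(is.null), results)
  sessions <- sessions_to_df(results)
  long <- do.call(rbind, lapply(results, as.data.frame))
  sessions_path <- file.path(out_dir, "sessions_wide.tsv")
  long_path <- file.path(out_dir, "sessions_long.tsv")
  utils::write.table(sessions, sessions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")

  say("stage 3/4: population contrasts")
  pop_rows <- list()
  for (w in unique(sessions$window)) {
    for (par in c("rho", "epsilon", "eta", "xi", "theta_juice", "theta_side",
                  "theta_order", "error_rate", "mean_rt")) {
      pc <- tryCatch(
        population_contrast(sessions, par, w,
                            outlier_k = config$analysis$outlier_k,
                            ellipse_level = config$analysis$ellipse_level),
        stimchoice_error = function(e) NULL)
      if (is.null(pc)) next
      pop_rows[[length(pop_rows) + 1L]] <- data.frame(
        window = w, parameter = par, n = pc$n,
        mean_diff = pc$tests$mean_diff,
        p_wilcoxon = pc$tests$p_wilcoxon, p_ttest = pc$tests$p_ttest,
        n_outliers_removed = pc$n_outliers_removed,
        ellipse_center_x = if (is.null(pc$ellipse)) NA else pc$ellipse$center[1],
        ellipse_center_y = if (is.null(pc$ellipse)) NA else pc$ellipse$center[2],
        ellipse_axis1 = if (is.null(pc$ellipse)) NA else pc$ellipse$semi_axes[1],
        ellipse_axis2 = if (is.null(pc$ellipse)) NA else pc$ellipse$semi_axes[2],
        ellipse_angle = if (is.null(pc$ellipse)) NA else pc$ellipse$angle)
    }
  }
  population <- do.call(rbind, pop_rows)
  population_path <- file.path(out_dir, "population.tsv")
  utils::write.table(population, population_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")

  say("stage 4/4: effect table")
  effects <- effect_table(sessions, alpha = config$analysis$alpha,
                          outlier_k = config$analysis$outlier_k)
  effects_path <- file.path(out_dir, "effects.tsv")
  utils::write.table(effects, effects_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")

  config_path <- file.path(out_dir, "config.json")
  write_config(config, config_path)
  run_manifest <- list(
    package = "stimchoice",
    package_version = as.character(utils::packageVersion("stimchoice")),
    r_version = R.version.string,
    seed = seed,
    config_md5 = unname(tools::md5sum(config_path)),
    n_sessions_analyzed = nrow(sessions),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE))
  manifest_json <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(run_manifest, manifest_json, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(sessions = sessions, effects = effects,
                 population = population,
                 paths = list(trials = trials_path,
                              ground_truth = manifest_path,
                              sessions_wide = sessions_path,
                              sessions_long = long_path,
                              population = population_path,
                              effects = effects_path,
                              config = config_path,
                              run_manifest = manifest_json)))
}
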