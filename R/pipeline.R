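# End-to-end orchestration: simulate (optional) -> sessionize -> metrics ->
# permutation nulls -> multimodel inference, with a machine-readable run log.

#' Default pipeline configuration
#'
#' @param out_dir Directory for all outputs.
#' @param detections Path to an existing detection CSV; `NULL` simulates
#'   one (requires `simulate = TRUE`).
#' @param simulate Simulate the inputs?
#' @param seed Master seed for every stochastic stage.
#' @param gap_threshold Sessionization merge threshold (seconds).
#' @param focal_sex,competitor_sex Sex combination under analysis.
#' @param n_rep Permutation replicates.
#' @param average Averaging method for [defense_mma()].
#' @param sim Simulator configuration ([sim_config()]).
#' @param treatment_year Year carrying the sucrose manipulation.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, detections = NULL,
                            simulate = is.null(detections), seed = 1L,
                            gap_threshold = 21, focal_sex = "M",
                            competitor_sex = "M", n_rep = 100L,
                            average = "zero", sim = sim_config(),
                            treatment_year = 2009L) {
  if (!simulate && is.null(detections))
    stop("config error: either supply a detections path or set simulate",
         call. = FALSE)
  structure(list(out_dir = out_dir, detections = detections,
                 simulate = simulate, seed = as.integer(seed),
                 gap_threshold = gap_threshold, focal_sex = focal_sex,
                 competitor_sex = competitor_sex, n_rep = as.integer(n_rep),
                 average = average, sim = sim,
                 treatment_year = as.integer(treatment_year)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional), sessionize, metrics, permutation nulls and
#' multimodel inference, writing every intermediate table plus a
#' machine-readable run log (seeds, package version, row counts at each
#' eligibility filter) into `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run directory, the `defense_mma`
#'   object, both `perm_test` objects and the run log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  log <- list(package_version = as.character(utils::packageVersion(
    "feederdefense")), seed = config$seed, stages = list())

  if (config$simulate) {
    grid <- make_grid(seed = config$seed)
    cfg <- config$sim
    schedule <- make_treatment_schedule(config$treatment_year,
                                        seed = config$seed, grid = grid)
    pop <- simulate_population(grid, cfg, seed = config$seed)
    detections <- simulate_detection_stream(pop, grid, schedule, cfg,
                                            seed = config$seed + 1L)
    utils::write.csv(grid, p("grid.csv"), row.names = FALSE)
    utils::write.csv(schedule, p("schedule.csv"), row.names = FALSE)
    utils::write.csv(pop, p("population.csv"), row.names = FALSE)
    write_detections(detections, p("detections.csv"))
    birds <- pop[c("tag_id", "sex", "age_class")]
    feeders <- grid
  } else {
    detections <- read_detections(config$detections)
    birds <- utils::read.csv(p("birds.csv"), stringsAsFactors = FALSE)
    feeders <- utils::read.csv(p("feeders.csv"), stringsAsFactors = FALSE)
    schedule <- NULL
    if (file.exists(p("schedule.csv"))) {
      schedule <- utils::read.csv(p("schedule.csv"),
                                  stringsAsFactors = FALSE)
      schedule$week_start <- as.Date(schedule$week_start)
      schedule$week_end <- as.Date(schedule$week_end)
    }
  }
  log$stages$detections <- list(rows = nrow(detections))

  visits <- detections_to_visits(detections,
                                 gap_threshold = config$gap_threshold)
  write_visits(visits, p("visits.csv"))
  log$stages$sessionize <- list(
    rows = nrow(visits), readings = sum(visits$n_readings),
    gap_threshold = config$gap_threshold)

  tab <- assemble_analysis_table(visits, birds, feeders, schedule,
                                 focal_sex = config$focal_sex,
                                 competitor_sex = config$competitor_sex)
  utils::write.csv(tab, p("analysis_table.csv"), row.names = FALSE)
  log$stages$metrics <- attr(tab, "filter_counts")

  # permutation nulls on adult visits of the competitor sex
  adult <- birds$tag_id[birds$age_class == "adult" &
                          birds$sex == config$competitor_sex]
  pv <- visits[visits$tag_id %in% adult, , drop = FALSE]
  perm_conc <- null_concentration(pv, n_rep = config$n_rep,
                                  seed = config$seed + 2L)
  perm_dom <- null_dominance(pv, n_rep = config$n_rep,
                             seed = config$seed + 3L)
  for (nm in c("perm_conc", "perm_dom")) {
    x <- get(nm)
    utils::write.csv(
      data.frame(statistic = x$statistic, observed = x$observed,
                 null_mean = x$null_mean, null_sd = x$null_sd,
                 p_value = x$p_value, n_rep = x$n_rep),
      p(paste0(nm, ".csv")), row.names = FALSE)
    utils::write.csv(data.frame(replicate = seq_len(x$n_rep),
                                value = x$null_values),
                     p(paste0(nm, "_null.csv")), row.names = FALSE)
  }
  log$stages$randomize <- list(n_rep = config$n_rep,
                               p_concentration = perm_conc$p_value,
                               p_dominance = perm_dom$p_value)

  fit <- defense_mma(tab, average = config$average)
  utils::write.csv(fit$selection, p("model_selection.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fit$averaged),
                   p("averaged_coefficients.csv"), row.names = FALSE)
  utils::write.csv(fit$blups, p("blup_slopes.csv"), row.names = FALSE)
  log$stages$inference <- list(
    n_rows = fit$n, n_individuals = fit$n_individuals,
    best_model = fit$selection$model_id[1],
    best_weight = fit$selection$weight[1])

  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(out_dir = config$out_dir, fit = fit,
                 perm_concentration = perm_conc, perm_dominance = perm_dom,
                 log = log))
}
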