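#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()]: `sim` holds
#' [simulation_config()] overrides (or `data_csv`, a path to an existing
#' trial CSV), `filters` the preprocessing thresholds, `fit` the
#' [hier_spec()] sampler/prior overrides, `rt` the BEST sampler settings,
#' `fixations` the bootstrap settings. Unknown keys are rejected.
#'
#' @param ... Named top-level sections (`sim`, `filters`, `fit`, `rt`,
#'   `fixations`, `seed`).
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(...)
  known <- c("sim", "filters", "fit", "rt", "fixations", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  defaults <- list(sim = list(), filters = list(), fit = list(),
                   rt = list(), fixations = list(), seed = 1)
  for (k in known) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  sub_known <- list(
    sim = c(names(formals(simulation_config)), "data_csv"),
    filters = c("accuracy_threshold", "rt_max_ms", "rt_min_ms", "main_only"),
    fit = names(formals(hier_spec)),
    rt = c("chains", "tune", "draws"),
    fixations = c("n_boot", "mass"))
  for (k in names(sub_known)) {
    bad <- setdiff(names(cfg[[k]]), sub_known[[k]])
    if (length(bad))
      stop(sprintf("unknown field(s) in '%s': %s", k,
                   paste(bad, collapse = ", ")))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose top-level keys match
#'   [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# md5 of the canonicalised configuration, so every output file can declare
# which configuration produced it
.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
}

#' Write / read the trial-table CSV schema
#'
#' One row per trial with the documented header (`participant`, `block`,
#' `block_type`, `block_start`, `trial`, `cycle_pos`, `phase`, `n_star`,
#' `n_pentagon`, `plateau`, `choice`, `digit_star`, `digit_pentagon`,
#' `digit_reported`, `correct`, `rt_ms`).
#'
#' @param trials Trial data.frame.
#' @param path Output CSV path.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("correct" %in% names(out)) out$correct <- as.logical(out$correct)
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> hierarchical fit ->
#' RT comparison -> fixation analyses -> report. Writes CSV intermediates
#' and JSON summaries into `out_dir`; every JSON output carries the
#' configuration hash and the seed that produced it. Any stage failure
#' aborts with an error naming the stage.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("acvs_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  stamp <- list(config_hash = hash, seed = config$seed,
                r_version = as.character(getRversion()),
                package_version = as.character(utils::packageVersion("acvsadapt")))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  study <- stage("simulate", {
    if (!is.null(config$sim$data_csv)) {
      list(trials = read_trials_csv(config$sim$data_csv),
           fixations = NULL, displays = NULL, truth = NULL)
    } else {
      sim_args <- config$sim
      sim_args$seed <- config$seed
      simulate_study(do.call(simulation_config, sim_args))
    }
  })
  write_trials_csv(study$trials, file.path(out_dir, "trials.csv"))

  fl <- config$filters
  pre <- stage("preprocess", preprocess_choices(
    study$trials,
    threshold = fl$accuracy_threshold %||% 0.75,
    rt_max_ms = fl$rt_max_ms %||% 5000,
    main_only = fl$main_only %||% TRUE))
  .write_json(c(stamp, attr(pre, "exclusion_report")),
              file.path(out_dir, "exclusions.json"))

  fit <- stage("fit", {
    fit_args <- config$fit
    fit_args$seed <- fit_args$seed %||% config$seed
    fit_hierarchical(pre, do.call(hier_spec, fit_args))
  })
  .write_json(c(stamp, list(summary = fit$summary,
                            warnings = fit$warnings)),
              file.path(out_dir, "fit_summary.json"))
  utils::write.csv(fit$participant,
                   file.path(out_dir, "participant_estimates.csv"),
                   row.names = FALSE)

  rt <- stage("rt", {
    ra <- config$rt
    rt_phase_comparison(pre, chains = ra$chains %||% 3,
                        tune = ra$tune %||% 500,
                        draws = ra$draws %||% 1000,
                        seed = config$seed)
  })
  .write_json(c(stamp, list(
    transition = rt$group_a, plateau = rt$group_b,
    difference = rt$difference)),
    file.path(out_dir, "rt_best.json"))

  fixres <- NULL
  if (!is.null(study$fixations)) {
    fixres <- stage("fixations", {
      ftrials <- exclude_fast_fixation_trials(
        pre, rt_min_ms = fl$rt_min_ms %||% 100)
      fx <- assign_fixation_table(study$fixations, study$displays)
      list(normalized = normalized_shape_proportions(fx, ftrials, "first"),
           chosen = chosen_vs_nonchosen_plateau(
             fx, ftrials, n_boot = config$fixations$n_boot %||% 2000,
             seed = config$seed),
           first_on_target = first_fixation_on_target_by_position(fx, ftrials))
    })
    utils::write.csv(fixres$normalized,
                     file.path(out_dir, "fixation_normalized_first.csv"),
                     row.names = FALSE)
    .write_json(c(stamp, list(chosen_vs_nonchosen = fixres$chosen)),
                file.path(out_dir, "fixation_chosen.json"))
  }

  .write_json(c(stamp, list(
    n_trials_in = nrow(study$trials),
    n_trials_analysed = nrow(pre),
    group_modes = as.list(stats::setNames(fit$summary$mode,
                                          fit$summary$param)))),
    file.path(out_dir, "report.json"))
  invisible(list(study = study, preprocessed = pre, fit = fit, rt = rt,
                 fixations = fixres, out_dir = out_dir,
                 config_hash = hash))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
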