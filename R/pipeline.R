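#' Read a pipeline run configuration
#'
#' YAML with optional sections `cohort` (arguments of [cohort_config()]
#' except `effect_map`), `task` ([task_config()] scalar arguments), `model`
#' ([model_config()]) and `fit` ([fit_config()] scalar arguments). Missing
#' sections fall back to package defaults. The shipped default lives at
#' `system.file("extdata", "default_config.yaml", package = "poporl")`.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @return a named list of resolved config objects.
#' @export
read_run_config <- function(path = NULL) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  grab <- function(section, fun, allowed) {
    args <- y[[section]]
    args <- if (is.null(args)) list() else args[intersect(names(args), allowed)]
    do.call(fun, args)
  }
  list(
    cohort = grab("cohort", cohort_config,
                  c("n_baseline", "cohort_split", "waves", "wave_spacing",
                    "retention", "maternal_hx_prev", "female_prob", "iq_mean",
                    "iq_sd", "onsite_prob", "dropout")),
    task = grab("task", task_config,
                c("n_trials", "presentations_per_deck", "starting_bank",
                  "timeout_seconds", "version", "timeout_prob")),
    model = grab("model", model_config,
                 c("outcome_scale", "fictive_updating", "fictive_attenuation")),
    fit = grab("fit", fit_config,
               c("backend", "tolerance", "max_iterations", "sd_floor"))
  )
}

PIPELINE_STAGES <- c("simulate", "fit", "score", "associate", "growth",
                     "report")

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> fit -> score -> associate -> growth -> report on
#' a synthetic study, writing every intermediate and final product as
#' CSV/JSON under `outdir` together with a run manifest (config echo, seed,
#' package version, stage status, file list). Stages can be restricted; a
#' stage whose inputs are not in memory reads them back from a previous run's
#' files in `outdir`, so a run can be resumed stage by stage. A refused
#' growth stage (e.g. a single-wave study) is recorded in the manifest and
#' surfaced as a warning; earlier stages still complete.
#'
#' @param config path to a run-configuration YAML, or a list from
#'   [read_run_config()], or `NULL` for defaults.
#' @param seed integer seed governing every stochastic stage.
#' @param outdir output directory (created if needed).
#' @param stages which stages to run, in pipeline order.
#' @return (invisibly) list with the in-memory stage products and the
#'   manifest.
#' @export
run_pipeline <- function(config = NULL, seed = 1, outdir = tempfile("poporl_"),
                         stages = PIPELINE_STAGES) {
  cfg <- if (is.character(config)) read_run_config(config)
         else if (is.null(config)) read_run_config() else config
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  status <- list()
  out <- list()
  need <- function(name, file, reader) {
    if (!is.null(out[[name]])) return(out[[name]])
    if (!file.exists(pth(file)))
      stop("resuming requires ", pth(file), " from a previous stage")
    reader(pth(file))
  }

  if ("simulate" %in% stages) {
    study <- simulate_study(cfg$cohort, cfg$task, cfg$model, seed = seed)
    out$sessions <- study$sessions
    out$demographics <- study$demographics
    out$ground_truth <- study$ground_truth
    write_sessions(study$sessions, pth("sessions.csv"))
    write.csv(study$demographics, pth("demographics.csv"), row.names = FALSE)
    write.csv(study$ground_truth, pth("ground_truth.csv"), row.names = FALSE)
    status$simulate <- "ok"
  }
  if ("fit" %in% stages) {
    sessions <- need("sessions", "sessions.csv", read_sessions)
    out$estimates <- fit_study(sessions, cfg$fit, cfg$model)
    write_estimates(out$estimates, pth("estimates.csv"))
    status$fit <- "ok"
  }
  if ("score" %in% stages) {
    sessions <- need("sessions", "sessions.csv", read_sessions)
    out$scores <- score_sessions(sessions)
    write_scores(out$scores, pth("scores.csv"))
    status$score <- "ok"
  }
  if ("associate" %in% stages) {
    est <- need("estimates", "estimates.csv", read.csv)
    sc <- need("scores", "scores.csv", read.csv)
    out$associations <- param_performance_associations(est, sc)
    write.csv(out$associations, pth("associations.csv"), row.names = FALSE)
    demo <- need("demographics", "demographics.csv", read.csv)
    waves <- sort(unique(est$wave))
    out$retest <- if (length(waves) < 2) {
      data.frame(metric = character(0), wave_a = integer(0),
                 wave_b = integer(0), r = numeric(0), n = integer(0),
                 band = character(0), note = character(0))
    } else do.call(rbind, lapply(
      c("net", PARAM_METRICS), function(m) {
        src <- if (m == "net") sc else est
        d <- data.frame(subject_id = src$subject_id, wave = src$wave,
                        value = src[[m]], stringsAsFactors = FALSE)
        cbind(metric = m, test_retest(d, waves), stringsAsFactors = FALSE)
      }))
    write.csv(out$retest, pth("retest.csv"), row.names = FALSE)
    status$associate <- "ok"
  }
  if ("growth" %in% stages) {
    est <- need("estimates", "estimates.csv", read.csv)
    sc <- need("scores", "scores.csv", read.csv)
    demo <- need("demographics", "demographics.csv", read.csv)
    long <- build_metric_table(est, sc, demo)
    growth <- tryCatch(run_trajectory_ladder(long), error = function(e) e)
    if (inherits(growth, "error")) {
      status$growth <- paste("refused:", conditionMessage(growth))
      warning("growth stage refused: ", conditionMessage(growth))
    } else {
      out$growth <- growth
      write.csv(growth$table, pth("growth_table.csv"), row.names = FALSE)
      write.csv(growth$summary, pth("growth_summary.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(age_fdr = growth$age_fdr, summary = growth$summary),
        pth("growth.json"), dataframe = "rows", digits = NA)
      status$growth <- "ok"
    }
  }
  if ("report" %in% stages) {
    status$report <- "ok"
    manifest <- list(
      package = "poporl",
      version = as.character(utils::packageVersion("poporl")),
      seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
      stages = status,
      config = list(
        cohort = cfg$cohort[setdiff(names(cfg$cohort), "effect_map")],
        task = cfg$task[c("n_trials", "presentations_per_deck",
                          "starting_bank", "version", "timeout_prob")],
        model = unclass(cfg$model),
        fit = cfg$fit[c("backend", "tolerance", "max_iterations", "sd_floor")]),
      files = list.files(outdir))
    jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    out$manifest <- manifest
  }
  out$status <- status
  out$outdir <- outdir
  invisible(out)
}
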