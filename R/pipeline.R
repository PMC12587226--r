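# End-to-end orchestration: simulate or load a dataset, build windows,
# compute CGM metrics, episode statistics, adjustment summaries and the
# deviation-association models, and write publication-style tables.
#
# Every run writes a run.log with the seed, a config fingerprint and the
# record counts at each stage, so session accounting can be reconciled
# (sessions in = sessions analyzed + sessions dropped, with reasons).

#' Run the full peri-exercise glycemia analysis
#'
#' @param config a [default_cohort_config()] to simulate from, or `NULL`
#'   when `input_dir` is given.
#' @param input_dir directory with a dataset in [write_dataset()] layout;
#'   mutually exclusive with `config`.
#' @param out_dir output directory for all artifacts.
#' @param morning_cutoff late-recovery end clock time, minutes past midnight.
#' @param pooling metric pooling mode, see [compute_window_metrics()].
#' @param fit_association fit the mixed-effects deviation models (set FALSE
#'   to skip the slowest stage).
#' @param write_simulated also write the simulated raw dataset to
#'   `out_dir/dataset/`.
#' @param quiet suppress console tables.
#' @return invisible list with `cohort`, `windows`, `metrics`,
#'   `episode_stats`, `adjustments`, `association`, `artifacts` (file paths).
#' @export
run_report <- function(config = NULL, input_dir = NULL, out_dir,
                       morning_cutoff = 480,
                       pooling = "readings",
                       fit_association = TRUE,
                       write_simulated = FALSE,
                       quiet = FALSE) {
  if (is.null(config) == is.null(input_dir)) {
    stop("provide exactly one of 'config' (simulate) or 'input_dir' (load)",
         call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  if (!is.null(config)) {
    cfg <- validate_cohort_config(config)
    cohort <- generate_cohort(cfg)
    note("mode: simulate (seed %d, config %s)", cfg$seed,
         fnv1a32(yaml::as.yaml(unclass(cfg))))
  } else {
    cohort <- read_dataset(input_dir)
    cohort$episodes <- classify_episode(cohort$episodes)
    note("mode: load from %s", input_dir)
  }
  note("participants: %d | sessions: %d | episodes: %d | carb intakes: %d",
       nrow(cohort$participants), nrow(cohort$sessions),
       nrow(cohort$episodes), nrow(cohort$carbs))

  windows <- cohort_window_partition(cohort$sessions,
                                     morning_cutoff = morning_cutoff)
  cohort$windows <- windows
  note("windows: %d labeled intervals over %d participants",
       nrow(windows), length(unique(windows$participant_id)))

  if (!is.null(config)) {
    cohort$traces <- synthesize_traces(cohort$config, cohort$sessions, windows)
  }
  if (is.null(cohort$traces)) {
    stop("no CGM traces available (cgm.csv missing)", call. = FALSE)
  }
  note("cgm readings: %d", nrow(cohort$traces))
  if (write_simulated && !is.null(config)) {
    write_dataset(cohort, file.path(out_dir, "dataset"))
  }

  artifacts <- character(0)
  keep_file <- function(p) artifacts <<- c(artifacts, p)

  metrics <- compute_window_metrics(cohort$traces, windows, pooling = pooling)
  metrics_table(metrics, file = file.path(out_dir, "metrics.csv"),
                quiet = quiet)
  keep_file(file.path(out_dir, "metrics.csv"))
  note("metric readings assigned: %d | excluded outside windows: %d",
       sum(metrics$n_readings), attr(metrics, "n_excluded"))

  stats_ep <- aggregate_episode_stats(cohort$sessions, cohort$episodes)
  jsonlite::write_json(unclass(stats_ep),
                       file.path(out_dir, "episode_stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "columnmajor")
  keep_file(file.path(out_dir, "episode_stats.json"))
  if (!quiet) print(stats_ep)

  prof <- adjustment_profiles(cohort$sessions, cohort$carbs)
  adj <- summarize_adjustments(prof)
  write.csv(prof, file.path(out_dir, "adjustments.csv"), row.names = FALSE,
            na = "")
  keep_file(file.path(out_dir, "adjustments.csv"))
  jsonlite::write_json(unclass(adj),
                       file.path(out_dir, "adjustment_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  keep_file(file.path(out_dir, "adjustment_summary.json"))
  if (!quiet) print(adj)
  note("adjustment data: %d sessions with, %d without",
       adj$n_sessions_with_adjustment_data,
       adj$n_sessions - adj$n_sessions_with_adjustment_data)

  association <- NULL
  if (fit_association) {
    association <- tryCatch(fit_deviation_models(cohort), error = function(e) e)
    if (inherits(association, "error")) {
      payload <- list(error = conditionMessage(association))
      note("association: not fitted (%s)", conditionMessage(association))
      association <- NULL
    } else {
      payload <- .association_json(association)
      note("association: %d sessions analyzed, %d dropped (missing adjustment data)",
           association$joint$n_sessions, association$n_sessions_dropped)
      if (!quiet) print(association$joint)
    }
    jsonlite::write_json(payload, file.path(out_dir, "association.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    keep_file(file.path(out_dir, "association.json"))
  }

  write_windows_csv(windows, file.path(out_dir, "windows.csv"))
  keep_file(file.path(out_dir, "windows.csv"))

  writeLines(log_lines, file.path(out_dir, "run.log"))
  keep_file(file.path(out_dir, "run.log"))

  invisible(list(cohort = cohort, windows = windows, metrics = metrics,
                 episode_stats = stats_ep, adjustments = adj,
                 association = association, artifacts = artifacts))
}

.association_json <- function(assoc) {
  strip <- function(fit) {
    list(coefficients = fit$coefficients,
         random_intercept_sd = fit$random_intercept_sd,
         loglik = fit$loglik, n_sessions = fit$n_sessions,
         n_participants = fit$n_participants, n_nodes = fit$n_nodes,
         converged = fit$converged)
  }
  list(joint = strip(assoc$joint),
       single = lapply(assoc$single, strip),
       n_sessions_dropped = assoc$n_sessions_dropped,
       notes = assoc$notes)
}
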