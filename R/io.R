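# Plain-CSV dataset interchange.
#
# Layout (all timestamps ISO-8601 local time, no timezone suffix):
#   participants.csv  participant_id, pump_brand, random_intercept,
#                     level2_share_effect
#   sessions.csv      one row per session; episode and carb sub-records live
#                     in companion long-format files keyed by session_id
#   episodes.csv      session_id, participant_id, phase, min_glucose, level,
#                     symptom_class, detection, interruption
#   carbs.csv         session_id, participant_id, when, offset_min, grams
#   cgm.csv           participant_id, timestamp, glucose_mg_dl

#' Write a synthetic (or real) dataset to a directory of CSV files
#'
#' @param cohort a `pg_cohort` list (`participants`, `sessions`, `episodes`,
#'   `carbs`, optionally `traces`).
#' @param out_dir output directory, created if needed.
#' @return invisible character vector of the files written.
#' @export
write_dataset <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE, na = "")
    files <<- c(files, path)
  }
  wr(cohort$participants, "participants.csv")
  ss <- cohort$sessions
  ss$start <- pg_format_time(ss$start)
  wr(ss, "sessions.csv")
  wr(cohort$episodes, "episodes.csv")
  wr(cohort$carbs, "carbs.csv")
  if (!is.null(cohort$traces)) {
    tr <- cohort$traces
    tr$timestamp <- pg_format_time(tr$timestamp)
    wr(tr, "cgm.csv")
  }
  invisible(files)
}

.read_csv_typed <- function(path, col_classes) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = col_classes, na.strings = "")
  df
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the CSV files.
#' @return a `pg_cohort` list (without `config`); `traces` is present when
#'   `cgm.csv` exists.
#' @export
read_dataset <- function(dir) {
  need <- c("participants.csv", "sessions.csv", "episodes.csv", "carbs.csv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop("missing dataset file: ", file.path(dir, f), call. = FALSE)
    }
  }
  participants <- .read_csv_typed(file.path(dir, "participants.csv"),
                                  c(participant_id = "character",
                                    pump_brand = "character",
                                    random_intercept = "numeric",
                                    level2_share_effect = "numeric"))
  sessions <- .read_csv_typed(file.path(dir, "sessions.csv"),
                              c(session_id = "character",
                                participant_id = "character",
                                start = "character",
                                duration_hours = "numeric",
                                activity_type = "character",
                                borg_category = "character",
                                temp_target_offset_min = "numeric",
                                adjustment_missing = "logical"))
  sessions$start <- pg_time(sessions$start)
  episodes <- .read_csv_typed(file.path(dir, "episodes.csv"),
                              c(session_id = "character",
                                participant_id = "character",
                                phase = "character", min_glucose = "numeric",
                                level = "integer",
                                symptom_class = "character",
                                detection = "character",
                                interruption = "character"))
  carbs <- .read_csv_typed(file.path(dir, "carbs.csv"),
                           c(session_id = "character",
                             participant_id = "character",
                             when = "character", offset_min = "numeric",
                             grams = "numeric"))
  out <- list(participants = participants, sessions = sessions,
              episodes = episodes, carbs = carbs)
  cgm_path <- file.path(dir, "cgm.csv")
  if (file.exists(cgm_path)) {
    traces <- .read_csv_typed(cgm_path, c(participant_id = "character",
                                          timestamp = "character",
                                          glucose_mg_dl = "integer"))
    traces$timestamp <- pg_time(traces$timestamp)
    out$traces <- traces
  }
  class(out) <- "pg_cohort"
  out
}

#' Write a labeled window partition to CSV
#'
#' @param windows result of [cohort_window_partition()].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_windows_csv <- function(windows, path) {
  w <- windows
  w$start <- pg_format_time(w$start)
  w$end <- pg_format_time(w$end)
  write.csv(w, path, row.names = FALSE, na = "")
  invisible(path)
}
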