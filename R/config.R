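# Synthetic cohort configuration.
#
# The default calibration encodes the descriptive marginals of a one-month,
# 86-participant free-living cohort of adults with type 1 diabetes on
# automated insulin delivery (~950 logged activity sessions): per-window
# glucose band occupancies, session-level hypoglycemia rates by activity
# type, temporary-target usage, and carbohydrate-intake prevalences and
# amounts. Every probability is an explicit config field so alternative
# scenarios are one edit away.

#' Default synthetic cohort configuration
#'
#' Returns a fully populated `pg_cohort_config`. All fields can be
#' overridden via `...`; the result is validated with
#' [validate_cohort_config()].
#'
#' @param seed integer master seed driving every random draw.
#' @param ... named overrides of any config field.
#' @return a validated list of class `pg_cohort_config`.
#' @export
default_cohort_config <- function(seed = 20240601, ...) {
  cfg <- list(
    n_participants = 86L,
    study_days = 30L,
    study_start = "2024-06-01",
    sessions_per_week_range = c(2L, 3L),
    session_duration_hours = list(mean = 1.5, sd = 1.1, min = 0.25, max = 8),
    pump_brand_probs = c(Medtronic = 39, Tandem = 25, Ypsomed = 22) / 86,
    activity_type_probs = c(aerobic = 692, anaerobic = 85, mixed = 144) / 921,
    borg_category_probs = c(nothing = 16, low = 257, moderate = 584, high = 88) / 945,
    band_occupancy_by_window = list(
      PRE    = c(p_lt54 = 0.002, p_54_69 = 0.008, p_70_180 = 0.74,
                 p_181_250 = 0.20, p_gt250 = 0.05),
      DURING = c(p_lt54 = 0.02, p_54_69 = 0.04, p_70_180 = 0.69,
                 p_181_250 = 0.20, p_gt250 = 0.05),
      EARLY  = c(p_lt54 = 0.015, p_54_69 = 0.035, p_70_180 = 0.69,
                 p_181_250 = 0.21, p_gt250 = 0.05),
      LATE   = c(p_lt54 = 0.01, p_54_69 = 0.03, p_70_180 = 0.74,
                 p_181_250 = 0.18, p_gt250 = 0.04),
      NONEX  = c(p_lt54 = 0.01, p_54_69 = 0.02, p_70_180 = 0.73,
                 p_181_250 = 0.19, p_gt250 = 0.05)
    ),
    cgm_persistence = 0.10,
    cgm_missing_session_prob = 240 / 954,
    hypo_prob_by_type_and_level = list(
      aerobic   = c(level1 = 2 / 3 * 0.20, level2 = 1 / 3 * 0.20),
      anaerobic = c(level1 = 2 / 3 * 0.12, level2 = 1 / 3 * 0.12),
      mixed     = c(level1 = 2 / 3 * 0.21, level2 = 1 / 3 * 0.21)
    ),
    symptom_class_probs = c(adrenergic = 0.10, neuroglycopenic = 0.13,
                            combined = 0.42, asymptomatic = 0.35),
    interruption_probs = c(none = 0.69, temporary = 0.19, permanent = 0.12),
    episode_phase_probs = c(before = 0.10, during = 0.55, after = 0.35),
    episode_missing_glucose_prob = 0.10,
    temp_target_category_probs = c(activated_ge_1h_before = 0.27,
                                   activated_lt_1h_or_during = 0.46,
                                   none = 0.27),
    adjustment_missing_prob = 130 / 954,
    carb_before_prob = 342 / 954,
    carb_during_prob = 257 / 954,
    carb_before_grams = list(meanlog = log(20), sdlog = 0.51),
    carb_during_n_probs = c(`1` = 0.45, `2` = 0.385, `3` = 0.165),
    carb_during_event_grams = list(meanlog = 2.75, sdlog = 0.40),
    deviation_effect_log_odds = c(late_or_no_temp_target = 0,
                                  snack_within_1h_before = 0,
                                  single_intake_gt20g_during = 0),
    random_intercept_sd = 1.0,
    level2_share_sd = 2.0,
    seed = as.integer(seed)
  )
  override <- list(...)
  if (length(override)) {
    unknown <- setdiff(names(override), names(cfg))
    if (length(unknown)) {
      stop("unknown config field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(override)] <- override
  }
  validate_cohort_config(cfg)
}

#' Validate a cohort configuration
#'
#' Checks counts, probability vectors (each must sum to 1 within 1e-9), band
#' occupancies (5 nonnegative entries summing to 1) and distribution specs.
#' Errors name the offending field.
#'
#' @param cfg a cohort-config list.
#' @return the config, classed `pg_cohort_config`, invisibly usable onward.
#' @export
validate_cohort_config <- function(cfg) {
  num1 <- function(x, nm, lo = -Inf, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi) {
      stop(sprintf("config field '%s' is invalid", nm), call. = FALSE)
    }
  }
  num1(cfg$n_participants, "n_participants", lo = 1)
  num1(cfg$study_days, "study_days", lo = 1)
  if (length(cfg$sessions_per_week_range) != 2 ||
      any(cfg$sessions_per_week_range < 0) ||
      cfg$sessions_per_week_range[1] > cfg$sessions_per_week_range[2]) {
    stop("config field 'sessions_per_week_range' is invalid", call. = FALSE)
  }
  dd <- cfg$session_duration_hours
  if (!all(c("mean", "sd", "min") %in% names(dd)) || dd$sd < 0 || dd$min <= 0) {
    stop("config field 'session_duration_hours' is invalid", call. = FALSE)
  }
  check_probs(cfg$pump_brand_probs, "pump_brand_probs", 3)
  check_probs(cfg$activity_type_probs, "activity_type_probs", 3)
  check_probs(cfg$borg_category_probs, "borg_category_probs", 4)
  if (!identical(sort(names(cfg$band_occupancy_by_window)), sort(PG_CLASSES))) {
    stop("config field 'band_occupancy_by_window' must name all five window classes",
         call. = FALSE)
  }
  for (cl in names(cfg$band_occupancy_by_window)) {
    check_probs(cfg$band_occupancy_by_window[[cl]],
                paste0("band_occupancy_by_window$", cl), 5)
  }
  num1(cfg$cgm_persistence, "cgm_persistence", lo = 0, hi = 1 - 1e-12)
  num1(cfg$cgm_missing_session_prob, "cgm_missing_session_prob", 0, 1)
  for (ty in c("aerobic", "anaerobic", "mixed")) {
    p <- cfg$hypo_prob_by_type_and_level[[ty]]
    if (is.null(p) || length(p) != 2 || any(p < 0) || sum(p) >= 1) {
      stop(sprintf("config field 'hypo_prob_by_type_and_level$%s' is invalid", ty),
           call. = FALSE)
    }
  }
  check_probs(cfg$symptom_class_probs, "symptom_class_probs", 4)
  check_probs(cfg$interruption_probs, "interruption_probs", 3)
  check_probs(cfg$episode_phase_probs, "episode_phase_probs", 3)
  num1(cfg$episode_missing_glucose_prob, "episode_missing_glucose_prob", 0, 1)
  check_probs(cfg$temp_target_category_probs, "temp_target_category_probs", 3)
  num1(cfg$adjustment_missing_prob, "adjustment_missing_prob", 0, 1)
  num1(cfg$carb_before_prob, "carb_before_prob", 0, 1)
  num1(cfg$carb_during_prob, "carb_during_prob", 0, 1)
  check_probs(cfg$carb_during_n_probs, "carb_during_n_probs")
  if (length(cfg$deviation_effect_log_odds) != 3 ||
      any(!is.finite(cfg$deviation_effect_log_odds))) {
    stop("config field 'deviation_effect_log_odds' is invalid", call. = FALSE)
  }
  num1(cfg$random_intercept_sd, "random_intercept_sd", lo = 0)
  num1(cfg$level2_share_sd, "level2_share_sd", lo = 0)
  num1(cfg$seed, "seed")
  structure(cfg, class = "pg_cohort_config")
}

#' Read a cohort configuration from YAML or JSON
#'
#' The file mirrors the config field names exactly; omitted fields fall back
#' to the defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return validated `pg_cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  raw <- .relist_config(raw)
  do.call(default_cohort_config,
          c(list(seed = if (is.null(raw$seed)) 20240601 else raw$seed),
            raw[setdiff(names(raw), "seed")]))
}

#' Write a cohort configuration to YAML or JSON
#'
#' @param cfg a `pg_cohort_config`.
#' @param path destination ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(cfg, path) {
  # named atomic vectors serialize as maps (lists) so names survive the trip
  to_plain <- function(x) {
    if (is.list(x)) lapply(x, to_plain)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  plain <- to_plain(unclass(cfg))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(plain, path, precision = 15)
  } else {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

# yaml/json round-trips drop vector names in some layouts; restore the ones
# validation relies on when entries arrive as named lists
.relist_config <- function(raw) {
  vecfields <- c("pump_brand_probs", "activity_type_probs",
                 "borg_category_probs", "symptom_class_probs",
                 "interruption_probs", "episode_phase_probs",
                 "temp_target_category_probs", "carb_during_n_probs",
                 "deviation_effect_log_odds", "sessions_per_week_range")
  for (f in intersect(vecfields, names(raw))) {
    raw[[f]] <- unlist(raw[[f]])
  }
  if ("band_occupancy_by_window" %in% names(raw)) {
    raw$band_occupancy_by_window <- lapply(raw$band_occupancy_by_window, unlist)
  }
  if ("hypo_prob_by_type_and_level" %in% names(raw)) {
    raw$hypo_prob_by_type_and_level <-
      lapply(raw$hypo_prob_by_type_and_level, unlist)
  }
  raw
}

#' @export
print.pg_cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d participants, %d days, seed %d\n",
              x$n_participants, x$study_days, x$seed))
  cat(sprintf("  sessions/week %d-%d, duration ~N(%.2g, %.2g) h (min %.2g)\n",
              x$sessions_per_week_range[1], x$sessions_per_week_range[2],
              x$session_duration_hours$mean, x$session_duration_hours$sd,
              x$session_duration_hours$min))
  occ <- do.call(rbind, x$band_occupancy_by_window)
  cat("  band occupancy by window class:\n")
  print(round(occ, 3))
  invisible(x)
}
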