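# Behavioural adjustment classification: temporary-target timing and
# carbohydrate intake around sessions, plus guideline-deviation flags.
#
# Exercise-management guidance encoded here: activate a raised temporary
# glucose target at least 1 h before the session; avoid unannounced snacks in
# the hour before; limit carbohydrate intake during exercise to <= 20 g at a
# time. Deviation flags mark sessions breaking each rule.

PG_TT_CATEGORIES <- c("activated_ge_1h_before", "activated_lt_1h_or_during", "none")

#' Temporary-target timing category
#'
#' @param offset_min activation time in minutes relative to session start
#'   (negative = before; `NA` = no activation). Vectorized.
#' @param session_end_min session duration in minutes (scalar or vector);
#'   activation after session end is invalid.
#' @return character vector of categories: `activated_ge_1h_before`
#'   (activation at least 1 h before start, offset `<= -60`),
#'   `activated_lt_1h_or_during`, or `none`.
#' @export
temp_target_category <- function(offset_min, session_end_min = Inf) {
  if (any(!is.na(offset_min) & offset_min > session_end_min)) {
    stop("temporary-target activation after session end", call. = FALSE)
  }
  ifelse(is.na(offset_min), "none",
         ifelse(offset_min <= -60, "activated_ge_1h_before",
                "activated_lt_1h_or_during"))
}

#' Build per-session adjustment profiles
#'
#' @param sessions data.frame with `session_id`, `duration_hours`,
#'   `temp_target_offset_min` (NA = none) and `adjustment_missing` (logical;
#'   sessions whose temporary-target data were not recorded).
#' @param carbs long-format data.frame with `session_id`, `when`
#'   (`"before"`/`"during"`), `offset_min` (minutes before start for
#'   `before`, minutes after start for `during`), `grams`.
#' @return data.frame, one row per session: `session_id`,
#'   `temp_target_category` (NA when adjustment data are missing),
#'   `total_carbs_before_g`, `total_carbs_during_g`, `n_intakes_before`,
#'   `n_intakes_during`, and the three deviation flags.
#' @export
adjustment_profiles <- function(sessions, carbs) {
  stopifnot(all(c("session_id", "duration_hours") %in% names(sessions)))
  if (nrow(carbs)) {
    stopifnot(all(c("session_id", "when", "offset_min", "grams") %in% names(carbs)))
    if (any(carbs$grams <= 0)) stop("carbohydrate grams must be positive", call. = FALSE)
    if (!all(carbs$when %in% c("before", "during"))) {
      stop("carb intake 'when' must be 'before' or 'during'", call. = FALSE)
    }
    before <- carbs[carbs$when == "before", , drop = FALSE]
    if (any(before$offset_min <= 0 | before$offset_min > 120)) {
      stop("pre-exercise intakes must fall in the (0, 120] min window before start",
           call. = FALSE)
    }
    dur_min <- round(sessions$duration_hours * 60)[match(carbs$session_id,
                                                         sessions$session_id)]
    during <- carbs$when == "during"
    if (any(during & (carbs$offset_min < 0 | carbs$offset_min > dur_min))) {
      stop("during-exercise intakes must fall within the session interval",
           call. = FALSE)
    }
  }
  miss <- if ("adjustment_missing" %in% names(sessions)) {
    sessions$adjustment_missing
  } else rep(FALSE, nrow(sessions))
  off <- if ("temp_target_offset_min" %in% names(sessions)) {
    sessions$temp_target_offset_min
  } else rep(NA_real_, nrow(sessions))
  ttc <- temp_target_category(off, round(sessions$duration_hours * 60))
  ttc[miss] <- NA_character_

  agg <- function(sub, f, default) {
    if (!nrow(sub)) return(rep(default, nrow(sessions)))
    v <- tapply(sub$grams, sub$session_id, f)
    out <- v[match(sessions$session_id, names(v))]
    out[is.na(out)] <- default
    as.numeric(out)
  }
  b <- carbs[carbs$when == "before", , drop = FALSE]
  d <- carbs[carbs$when == "during", , drop = FALSE]
  tot_b <- agg(b, sum, 0)
  tot_d <- agg(d, sum, 0)
  n_b <- agg(b, length, 0)
  n_d <- agg(d, length, 0)

  snack1h <- rep(FALSE, nrow(sessions))
  if (nrow(b)) {
    s1 <- tapply(b$offset_min < 60, b$session_id, any)
    hit <- match(sessions$session_id, names(s1))
    snack1h[!is.na(hit)] <- s1[hit[!is.na(hit)]]
  }
  gt20 <- rep(FALSE, nrow(sessions))
  if (nrow(d)) {
    g1 <- tapply(d$grams > 20, d$session_id, any)
    hit <- match(sessions$session_id, names(g1))
    gt20[!is.na(hit)] <- g1[hit[!is.na(hit)]]
  }

  data.frame(
    session_id = sessions$session_id,
    temp_target_category = ttc,
    total_carbs_before_g = tot_b,
    total_carbs_during_g = tot_d,
    n_intakes_before = as.integer(n_b),
    n_intakes_during = as.integer(n_d),
    late_or_no_temp_target = ifelse(is.na(ttc), NA,
                                    ttc != "activated_ge_1h_before"),
    snack_within_1h_before = snack1h,
    single_intake_gt20g_during = gt20,
    stringsAsFactors = FALSE
  )
}

#' Guideline-deviation flags of one or more sessions
#'
#' @param profiles result of [adjustment_profiles()].
#' @return data.frame with `session_id` and logical columns
#'   `late_or_no_temp_target` (temporary target not activated at least 1 h
#'   before start; `NA` when adjustment data are missing),
#'   `snack_within_1h_before`, `single_intake_gt20g_during`.
#' @export
deviation_flags <- function(profiles) {
  data.frame(
    session_id = profiles$session_id,
    late_or_no_temp_target = ifelse(is.na(profiles$temp_target_category), NA,
                                    profiles$temp_target_category !=
                                      "activated_ge_1h_before"),
    snack_within_1h_before = profiles$snack_within_1h_before,
    single_intake_gt20g_during = profiles$single_intake_gt20g_during,
    stringsAsFactors = FALSE
  )
}

#' Summarize adjustment behaviour over a cohort
#'
#' Temporary-target percentages use sessions with non-missing adjustment data
#' as denominator; carbohydrate percentages use all sessions (matching how
#' the two blocks are recorded in the logbook). Medians and IQRs (25th/75th
#' percentiles, linear interpolation) are computed over sessions with at
#' least one intake of the respective kind.
#'
#' @param profiles result of [adjustment_profiles()].
#' @return list of class `pg_adjustment_summary`.
#' @export
summarize_adjustments <- function(profiles) {
  has_adj <- !is.na(profiles$temp_target_category)
  n_adj <- sum(has_adj)
  cat_tab <- vapply(PG_TT_CATEGORIES, function(ct) {
    if (n_adj > 0) 100 * sum(profiles$temp_target_category[has_adj] == ct) / n_adj
    else NA_real_
  }, numeric(1))

  n_all <- nrow(profiles)
  with_b <- profiles$n_intakes_before > 0
  with_d <- profiles$n_intakes_during > 0
  qs <- function(x) {
    if (!length(x)) return(c(median = NA_real_, q25 = NA_real_, q75 = NA_real_))
    q <- quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
    c(median = q[1], q25 = q[2], q75 = q[3])
  }
  out <- list(
    n_sessions = n_all,
    n_sessions_with_adjustment_data = n_adj,
    pct_temp_target_by_category = cat_tab,
    pct_temp_target_any = if (n_adj > 0) 100 - cat_tab[["none"]] else NA_real_,
    pct_sessions_carb_before = 100 * sum(with_b) / n_all,
    pct_sessions_carb_during = 100 * sum(with_d) / n_all,
    carb_before_g = qs(profiles$total_carbs_before_g[with_b]),
    carb_during_g = qs(profiles$total_carbs_during_g[with_d]),
    pct_sessions_gt20g_during = 100 * sum(profiles$single_intake_gt20g_during) / n_all
  )
  class(out) <- "pg_adjustment_summary"
  out
}

#' @export
print.pg_adjustment_summary <- function(x, ...) {
  cat(sprintf("Adjustment summary (%d sessions; %d with adjustment data)\n",
              x$n_sessions, x$n_sessions_with_adjustment_data))
  cat("  temporary target (% of sessions with data):\n")
  print(round(x$pct_temp_target_by_category))
  cat(sprintf("  carb intake before: %.0f%% of sessions, median %.1f g [%.1f; %.1f]\n",
              x$pct_sessions_carb_before, x$carb_before_g["median"],
              x$carb_before_g["q25"], x$carb_before_g["q75"]))
  cat(sprintf("  carb intake during: %.0f%% of sessions, median %.1f g [%.1f; %.1f]\n",
              x$pct_sessions_carb_during, x$carb_during_g["median"],
              x$carb_during_g["q25"], x$carb_during_g["q75"]))
  cat(sprintf("  sessions with a single during-intake > 20 g: %.0f%%\n",
              x$pct_sessions_gt20g_during))
  invisible(x)
}
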