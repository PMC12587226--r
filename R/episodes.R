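# Classification and aggregation of logbook-reported hypoglycemia episodes.
#
# An episode is level 2 when its lowest recorded glucose is < 54 mg/dL and
# level 1 otherwise (< 70 mg/dL by definition of a reported hypoglycemia).
# Episodes reported on symptoms alone, without any glucose reading, are
# assigned level 1 by convention and flagged as imputed rather than silently
# classified.

PG_PHASES <- c("before", "during", "after")
PG_SYMPTOMS <- c("adrenergic", "neuroglycopenic", "combined", "asymptomatic")
PG_DETECTION <- c("symptoms", "cgm", "capillary")
PG_INTERRUPT <- c("none", "temporary", "permanent")

#' Classify raw logbook episode records
#'
#' @param episodes data.frame with columns `session_id`, `phase`,
#'   `min_glucose` (mg/dL, may be NA), `symptom_class`, `detection`,
#'   `interruption`.
#' @return the same data.frame with columns `level` (1 or 2) and
#'   `level_imputed` (TRUE when no glucose reading was available and level 1
#'   was assigned by convention), after validation.
#' @export
classify_episode <- function(episodes) {
  req <- c("session_id", "phase", "min_glucose", "symptom_class",
           "detection", "interruption")
  stopifnot(all(req %in% names(episodes)))
  if (any(is.na(episodes$session_id) | episodes$session_id == "")) {
    stop("every episode must reference a session", call. = FALSE)
  }
  chk <- function(x, lv, nm) {
    if (!all(x %in% lv)) stop(sprintf("invalid %s value", nm), call. = FALSE)
  }
  chk(episodes$phase, PG_PHASES, "phase")
  chk(episodes$symptom_class, PG_SYMPTOMS, "symptom_class")
  chk(episodes$detection, PG_DETECTION, "detection")
  chk(episodes$interruption, PG_INTERRUPT, "interruption")
  g <- episodes$min_glucose
  if (any(!is.na(g) & (g < 40 | g >= 70))) {
    stop("episode min_glucose must be in [40, 70) mg/dL or NA", call. = FALSE)
  }
  bad <- episodes$symptom_class == "asymptomatic" & episodes$detection == "symptoms"
  if (any(bad)) {
    stop("asymptomatic episodes must be detected by cgm or capillary reading",
         call. = FALSE)
  }
  if (any(is.na(g) & episodes$symptom_class == "asymptomatic")) {
    stop("asymptomatic episodes require a glucose reading", call. = FALSE)
  }
  episodes$level <- ifelse(is.na(g), 1L, ifelse(g < 54, 2L, 1L))
  episodes$level_imputed <- is.na(g)
  episodes
}

#' Aggregate session- and participant-level hypoglycemia rates
#'
#' A session counts as hypoglycemic when it has at least one episode in any
#' phase (before/during/after are pooled); as level 2 when at least one of its
#' episodes is level 2. The symptomatic share is computed over hypoglycemic
#' sessions only. Stratified rates (by activity type, by perceived-intensity
#' category and level) use as denominator the sessions of the stratum with a
#' non-missing stratum variable.
#'
#' @param sessions data.frame with columns `session_id`, `participant_id`,
#'   `activity_type` (may be NA), `borg_category` (may be NA).
#' @param episodes classified episodes ([classify_episode()]).
#' @return list of class `pg_episode_stats`; percentages are on the 0-100
#'   scale.
#' @export
aggregate_episode_stats <- function(sessions, episodes) {
  episodes <- classify_episode(episodes)
  if (!all(episodes$session_id %in% sessions$session_id)) {
    stop("episode references a session absent from the session table",
         call. = FALSE)
  }
  n_sess <- nrow(sessions)
  lev_by_sess <- tapply(episodes$level, episodes$session_id, max)
  l1_by_sess <- tapply(episodes$level == 1, episodes$session_id, any)
  sympt_by_sess <- tapply(episodes$symptom_class != "asymptomatic",
                          episodes$session_id, any)
  interrupt_rank <- c(none = 0, temporary = 1, permanent = 2)
  int_by_sess <- tapply(interrupt_rank[episodes$interruption],
                        episodes$session_id, max)

  hypo <- sessions$session_id %in% episodes$session_id
  lev2 <- !is.na(match(sessions$session_id, names(lev_by_sess))) &
    lev_by_sess[match(sessions$session_id, names(lev_by_sess))] == 2
  lev2[is.na(lev2)] <- FALSE
  lev1 <- sessions$session_id %in% names(l1_by_sess)[l1_by_sess]

  n_hypo <- sum(hypo)
  sympt <- sympt_by_sess[match(sessions$session_id[hypo],
                               names(sympt_by_sess))]
  ints <- int_by_sess[match(sessions$session_id[hypo], names(int_by_sess))]

  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_

  by_type <- vapply(c("aerobic", "anaerobic", "mixed"), function(ty) {
    in_ty <- !is.na(sessions$activity_type) & sessions$activity_type == ty
    pct(sum(hypo & in_ty), sum(in_ty))
  }, numeric(1))

  borg_levels <- c("nothing", "low", "moderate", "high")
  by_borg <- sapply(c(1, 2), function(lv) {
    has_lv <- if (lv == 1) lev1 else lev2
    vapply(borg_levels, function(bc) {
      in_bc <- !is.na(sessions$borg_category) & sessions$borg_category == bc
      pct(sum(has_lv & in_bc), sum(in_bc))
    }, numeric(1))
  })
  colnames(by_borg) <- c("level1", "level2")

  part_any <- tapply(hypo, sessions$participant_id, any)
  part_lev2 <- tapply(lev2, sessions$participant_id, any)

  out <- list(
    n_sessions = n_sess,
    n_participants = length(unique(sessions$participant_id)),
    n_hypo_sessions = n_hypo,
    pct_sessions_any = pct(n_hypo, n_sess),
    pct_sessions_level1 = pct(sum(lev1), n_sess),
    pct_sessions_level2 = pct(sum(lev2), n_sess),
    pct_symptomatic_of_hypo_sessions = pct(sum(sympt), n_hypo),
    pct_interrupt_temporary = pct(sum(ints == 1), n_hypo),
    pct_interrupt_permanent = pct(sum(ints == 2), n_hypo),
    by_type = by_type,
    by_borg = by_borg,
    pct_participants_any = pct(sum(part_any), length(part_any)),
    pct_participants_level2 = pct(sum(part_lev2), length(part_lev2)),
    n_level_imputed = sum(episodes$level_imputed)
  )
  class(out) <- "pg_episode_stats"
  out
}

#' @export
print.pg_episode_stats <- function(x, ...) {
  cat(sprintf("Hypoglycemia episode summary (%d sessions, %d participants)\n",
              x$n_sessions, x$n_participants))
  cat(sprintf("  sessions with any episode : %d (%.0f%%)\n",
              x$n_hypo_sessions, x$pct_sessions_any))
  cat(sprintf("  level 1 / level 2 sessions: %.0f%% / %.0f%%\n",
              x$pct_sessions_level1, x$pct_sessions_level2))
  cat(sprintf("  symptomatic (of hypo)     : %.0f%%\n",
              x$pct_symptomatic_of_hypo_sessions))
  cat(sprintf("  interruption temp/perm    : %.0f%% / %.0f%%\n",
              x$pct_interrupt_temporary, x$pct_interrupt_permanent))
  cat(sprintf("  participants any / level 2: %.0f%% / %.0f%%\n",
              x$pct_participants_any, x$pct_participants_level2))
  cat("  by activity type (%):\n")
  print(round(x$by_type))
  cat("  by Borg category x level (%):\n")
  print(round(x$by_borg))
  invisible(x)
}
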