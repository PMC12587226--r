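# Peri-exercise window segmentation.
#
# Five window classes partition each participant's study span:
#   DURING  the logged session interval itself
#   EARLY   up to 3 h after session end (early recovery)
#   PRE     up to 2 h before session start
#   LATE    from the end of early recovery until the next 08:00 clock time,
#           or the next session's pre-window start, whichever comes first
#   NONEX   all remaining time
# Priority when windows of different sessions overlap:
#   DURING > EARLY > PRE > LATE > NONEX.
# EARLY outranks a following session's PRE (early recovery is a fixed +3 h
# without caveat; only LATE is subordinated to the next pre-window).
# All intervals are half-open [start, end) at minute resolution: a reading
# timestamped exactly on a boundary belongs to the later window.

PG_CLASSES <- c("PRE", "DURING", "EARLY", "LATE", "NONEX")
PRE_MIN <- 120L    # pre-exercise lookback, minutes
EARLY_MIN <- 180L  # early-recovery length, minutes

#' Session interval
#'
#' The half-open time interval `[start, start + duration)` covered by a logged
#' physical-activity session.
#'
#' @param start session start time (POSIXct or parseable string).
#' @param duration_hours positive session duration in hours.
#' @return data.frame with POSIXct columns `start`, `end`.
#' @export
session_interval <- function(start, duration_hours) {
  start <- pg_time(start)
  if (any(!is.finite(duration_hours)) || any(duration_hours <= 0)) {
    stop("session duration must be positive", call. = FALSE)
  }
  end <- pg_time_from_min(pg_min(start) + round(duration_hours * 60))
  data.frame(start = start, end = end)
}

# normalize a sessions data.frame -> epoch-minute matrix sorted by start
.session_minutes <- function(sessions) {
  stopifnot(all(c("session_id", "start", "duration_hours") %in% names(sessions)))
  iv <- session_interval(sessions$start, sessions$duration_hours)
  out <- data.frame(session_id = sessions$session_id,
                    s = pg_min(iv$start), e = pg_min(iv$end),
                    stringsAsFactors = FALSE)
  out <- out[order(out$s), , drop = FALSE]
  if (nrow(out) > 1) {
    bad <- which(out$s[-1] < out$e[-nrow(out)])
    if (length(bad)) {
      stop(sprintf("overlapping sessions: %s and %s",
                   out$session_id[bad[1]], out$session_id[bad[1] + 1]),
           call. = FALSE)
    }
  }
  out
}

#' Label a single timepoint with its peri-exercise window class
#'
#' Direct implementation of the window definitions (used as the reference
#' labelling; [build_window_partition()] computes the same labelling by
#' interval arithmetic). Ties across sessions are resolved toward the most
#' recent qualifying session: for EARLY/LATE the session with the latest end,
#' for PRE the session with the earliest upcoming start.
#'
#' @param t timestamp (POSIXct or parseable string), length 1.
#' @param sessions data.frame with columns `session_id`, `start`
#'   (POSIXct/string), `duration_hours`.
#' @param morning_cutoff clock time ending late recovery, minutes past
#'   midnight (default 480 = 08:00).
#' @return list with `window_class` (one of PRE, DURING, EARLY, LATE, NONEX)
#'   and `session_id` (NA for NONEX).
#' @export
label_timepoint <- function(t, sessions, morning_cutoff = 480) {
  tm <- pg_min(pg_time(t))
  stopifnot(length(tm) == 1)
  if (is.null(sessions) || nrow(sessions) == 0) {
    return(list(window_class = "NONEX", session_id = NA_character_))
  }
  sm <- .session_minutes(sessions)
  s <- sm$s; e <- sm$e; id <- sm$session_id

  hit <- which(s <= tm & tm < e)
  if (length(hit)) {
    return(list(window_class = "DURING", session_id = id[hit[1]]))
  }
  hit <- which(e <= tm & tm < e + EARLY_MIN)
  if (length(hit)) {
    k <- hit[which.max(e[hit])]
    return(list(window_class = "EARLY", session_id = id[k]))
  }
  hit <- which(s - PRE_MIN <= tm & tm < s)
  if (length(hit)) {
    k <- hit[which.min(s[hit])]
    return(list(window_class = "PRE", session_id = id[k]))
  }
  # LATE: after some session's early-recovery end, before that session's
  # cutoff = min(next morning_cutoff after early end, next session's PRE start)
  early_end <- e + EARLY_MIN
  bound <- next_clock_after(early_end, morning_cutoff)
  if (nrow(sm) > 1) {
    nxt_pre <- c(s[-1] - PRE_MIN, Inf)
    bound <- pmin(bound, nxt_pre)
  }
  hit <- which(early_end <= tm & tm < bound)
  if (length(hit)) {
    k <- hit[which.max(e[hit])]
    return(list(window_class = "LATE", session_id = id[k]))
  }
  list(window_class = "NONEX", session_id = NA_character_)
}

# ---- interval machinery (IRanges; half-open [a,b) minutes -> [a, b-1]) ----

.ir <- function(a, b) {
  keep <- b > a
  IRanges::IRanges(start = as.integer(a[keep]), end = as.integer(b[keep]) - 1L)
}

# subtract an IRanges set from one IRanges set
.ir_diff <- function(x, y) {
  if (length(y) == 0 || length(x) == 0) return(x)
  IRanges::setdiff(x, IRanges::reduce(y))
}

.ir_to_df <- function(ir, class, session_id) {
  if (length(ir) == 0) return(NULL)
  data.frame(window_class = class,
             start_min = IRanges::start(ir),
             end_min = IRanges::end(ir) + 1L,
             session_id = session_id,
             stringsAsFactors = FALSE)
}

#' Build the labeled window partition of a participant's study span
#'
#' Partitions `[span_start, span_end)` into maximal half-open windows labeled
#' PRE / DURING / EARLY / LATE / NONEX with the priority
#' DURING > EARLY > PRE > LATE > NONEX. The returned windows are disjoint,
#' sorted, and their union equals the span exactly; each window carries the
#' identifier of its owning session (NA for NONEX).
#'
#' @param sessions data.frame with columns `session_id`, `start`,
#'   `duration_hours` (may have zero rows).
#' @param span_start,span_end study span bounds (POSIXct or parseable string);
#'   every session must lie within the span.
#' @param morning_cutoff clock time ending late recovery, minutes past
#'   midnight (default 480 = 08:00).
#' @return data.frame with columns `window_class`, `start`, `end` (POSIXct),
#'   `session_id`, sorted by `start`.
#' @export
build_window_partition <- function(sessions, span_start, span_end,
                                   morning_cutoff = 480) {
  a <- pg_min(pg_time(span_start)); b <- pg_min(pg_time(span_end))
  if (!(a < b)) stop("span must satisfy start < end", call. = FALSE)
  empty <- is.null(sessions) || nrow(sessions) == 0
  if (!empty) {
    sm <- .session_minutes(sessions)
    if (any(sm$s < a) || any(sm$e > b)) {
      stop("sessions must lie within the study span", call. = FALSE)
    }
  }
  span <- .ir(a, b)
  if (empty) {
    out <- .ir_to_df(span, "NONEX", NA_character_)
    return(.finish_partition(out, a, b))
  }

  n <- nrow(sm)
  s <- sm$s; e <- sm$e; id <- sm$session_id
  during <- .ir(s, e)
  pieces <- list(.ir_to_df_each(during, "DURING", id))

  # EARLY: +3h after each end, minus any DURING, overlaps owned by the later
  # session (subtract later sessions' early candidates from earlier ones)
  early_cand <- lapply(seq_len(n), function(i) .ir(e[i], pmin(e[i] + EARLY_MIN, b)))
  early <- vector("list", n)
  for (i in seq_len(n)) {
    x <- .ir_diff(early_cand[[i]], during)
    if (i < n) {
      later <- do.call(c, early_cand[(i + 1):n])
      x <- .ir_diff(x, later)
    }
    early[[i]] <- x
    pieces[[length(pieces) + 1]] <- .ir_to_df(x, "EARLY", id[i])
  }
  early_all <- do.call(c, c(early_cand, list(IRanges::IRanges())))

  # PRE: -2h before each start, minus DURING and all EARLY candidates,
  # overlaps owned by the earlier (soonest-starting) session
  pre_cand <- lapply(seq_len(n), function(i) .ir(pmax(s[i] - PRE_MIN, a), s[i]))
  for (i in seq_len(n)) {
    x <- .ir_diff(pre_cand[[i]], during)
    x <- .ir_diff(x, early_all)
    if (i > 1) {
      earlier <- do.call(c, pre_cand[1:(i - 1)])
      x <- .ir_diff(x, earlier)
    }
    pieces[[length(pieces) + 1]] <- .ir_to_df(x, "PRE", id[i])
  }
  pre_all <- do.call(c, pre_cand)

  # LATE: from early-recovery end to min(next morning cutoff, next PRE start)
  early_end <- e + EARLY_MIN
  bound <- next_clock_after(early_end, morning_cutoff)
  if (n > 1) bound <- pmin(bound, c(s[-1] - PRE_MIN, Inf))
  for (i in seq_len(n)) {
    x <- .ir(max(early_end[i], a), min(bound[i], b))
    x <- .ir_diff(x, during)
    x <- .ir_diff(x, early_all)
    x <- .ir_diff(x, pre_all)
    pieces[[length(pieces) + 1]] <- .ir_to_df(x, "LATE", id[i])
  }

  covered <- .ir(a, b)
  used <- do.call(rbind, pieces)
  used_ir <- .ir(used$start_min, used$end_min)
  nonex <- .ir_diff(covered, used_ir)
  pieces[[length(pieces) + 1]] <- .ir_to_df(nonex, "NONEX", NA_character_)

  .finish_partition(do.call(rbind, pieces), a, b)
}

.ir_to_df_each <- function(ir, class, ids) {
  if (length(ir) == 0) return(NULL)
  data.frame(window_class = class,
             start_min = IRanges::start(ir), end_min = IRanges::end(ir) + 1L,
             session_id = ids, stringsAsFactors = FALSE)
}

.finish_partition <- function(df, a, b) {
  df <- df[order(df$start_min), , drop = FALSE]
  # merge maximal runs of equal (class, session_id) that touch
  if (nrow(df) > 1) {
    same <- df$window_class[-1] == df$window_class[-nrow(df)] &
      (df$session_id[-1] == df$session_id[-nrow(df)] |
         (is.na(df$session_id[-1]) & is.na(df$session_id[-nrow(df)]))) &
      df$start_min[-1] == df$end_min[-nrow(df)]
    same[is.na(same)] <- FALSE
    grp <- cumsum(c(TRUE, !same))
    df <- data.frame(
      window_class = tapply(df$window_class, grp, `[`, 1),
      start_min = as.numeric(tapply(df$start_min, grp, min)),
      end_min = as.numeric(tapply(df$end_min, grp, max)),
      session_id = as.character(tapply(df$session_id, grp, `[`, 1)),
      stringsAsFactors = FALSE)
    df <- df[order(df$start_min), , drop = FALSE]
  }
  # partition sanity: exact cover of [a, b)
  if (df$start_min[1] != a || df$end_min[nrow(df)] != b ||
      (nrow(df) > 1 && any(df$start_min[-1] != df$end_min[-nrow(df)]))) {
    stop("internal error: window partition does not cover the span", call. = FALSE)
  }
  rownames(df) <- NULL
  data.frame(window_class = factor(df$window_class, levels = PG_CLASSES),
             start = pg_time_from_min(df$start_min),
             end = pg_time_from_min(df$end_min),
             session_id = df$session_id,
             stringsAsFactors = FALSE)
}

#' Build window partitions for every participant of a cohort
#'
#' Applies [build_window_partition()] per participant. The study span follows
#' the CGM download convention: 15 days before the participant's first session
#' to 15 days after the end of their last session.
#'
#' @param sessions data.frame with columns `participant_id`, `session_id`,
#'   `start`, `duration_hours`.
#' @param morning_cutoff minutes past midnight ending late recovery
#'   (default 480).
#' @param buffer_days span margin around first/last session (default 15).
#' @return data.frame with columns `participant_id`, `window_class`, `start`,
#'   `end`, `session_id`.
#' @export
cohort_window_partition <- function(sessions, morning_cutoff = 480,
                                    buffer_days = 15) {
  stopifnot(nrow(sessions) > 0)
  parts <- lapply(split(sessions, sessions$participant_id), function(ss) {
    iv <- session_interval(ss$start, ss$duration_hours)
    a <- min(pg_min(iv$start)) - buffer_days * 1440
    b <- max(pg_min(iv$end)) + buffer_days * 1440
    w <- build_window_partition(ss, pg_time_from_min(a), pg_time_from_min(b),
                                morning_cutoff)
    cbind(participant_id = ss$participant_id[1], w)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Study span of each participant
#'
#' @inheritParams cohort_window_partition
#' @return data.frame with `participant_id`, `span_start`, `span_end`.
#' @export
study_spans <- function(sessions, buffer_days = 15) {
  sp <- lapply(split(sessions, sessions$participant_id), function(ss) {
    iv <- session_interval(ss$start, ss$duration_hours)
    data.frame(participant_id = ss$participant_id[1],
               span_start = pg_time_from_min(min(pg_min(iv$start)) - buffer_days * 1440),
               span_end = pg_time_from_min(max(pg_min(iv$end)) + buffer_days * 1440))
  })
  out <- do.call(rbind, sp)
  rownames(out) <- NULL
  out
}
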