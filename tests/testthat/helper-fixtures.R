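# In-code fixtures shared across test files.

# quick session-table builder: starts as "YYYY-MM-DD HH:MM" strings
make_sessions <- function(starts, duration_hours,
                          participant_id = "P001",
                          session_id = sprintf("%s-S%03d", participant_id,
                                               seq_along(starts)),
                          activity_type = "aerobic",
                          borg_category = "moderate") {
  data.frame(session_id = session_id,
             participant_id = participant_id,
             start = pg_time(starts),
             duration_hours = duration_hours,
             activity_type = activity_type,
             borg_category = borg_category,
             temp_target_offset_min = NA_real_,
             adjustment_missing = FALSE,
             stringsAsFactors = FALSE)
}

# small, fast cohort config for structural tests
tiny_config <- function(seed = 1, ...) {
  default_cohort_config(seed = seed, n_participants = 6L, study_days = 14L, ...)
}

# expand a window partition to per-minute labels over the span
partition_minute_labels <- function(windows) {
  lab <- character(0); sid <- character(0)
  for (i in seq_len(nrow(windows))) {
    n <- pg_min(windows$end[i]) - pg_min(windows$start[i])
    lab <- c(lab, rep(as.character(windows$window_class[i]), n))
    sid <- c(sid, rep(windows$session_id[i], n))
  }
  list(minutes = seq(pg_min(windows$start[1]),
                     length.out = length(lab)),
       class = lab, session_id = sid)
}

# brute-force per-minute labelling via the direct rule implementation
oracle_minute_labels <- function(sessions, span_start, span_end,
                                 morning_cutoff = 480) {
  mins <- seq(pg_min(pg_time(span_start)), pg_min(pg_time(span_end)) - 1)
  lab <- character(length(mins)); sid <- character(length(mins))
  for (i in seq_along(mins)) {
    r <- label_timepoint(pg_time_from_min(mins[i]), sessions, morning_cutoff)
    lab[i] <- r$window_class
    sid[i] <- r$session_id
  }
  list(minutes = mins, class = lab, session_id = sid)
}

# balanced two-arm dataset with no between-participant heterogeneity:
# 10 identical participants, each 10 exposed sessions (2 events) and
# 10 unexposed (1 event); sample OR = (20/80)/(10/90) = 2.25
balanced_or_data <- function() {
  do.call(rbind, lapply(1:10, function(i) data.frame(
    participant_id = sprintf("Q%02d", i),
    hypo = c(rep(1, 2), rep(0, 8), rep(1, 1), rep(0, 9)),
    flag = rep(c(TRUE, FALSE), each = 10))))
}

# random non-overlapping session sets for property tests (1-6 sessions over
# 3 days)
random_session_set <- function(n_sessions, origin = "2024-06-01") {
  o <- pg_min(pg_time(origin))
  repeat {
    starts <- sort(sample(0:(3 * 1440 - 181), n_sessions))
    durs <- sample(15:180, n_sessions, replace = TRUE)
    if (n_sessions == 1 || all(starts[-1] > (starts + durs)[-n_sessions])) {
      return(make_sessions(pg_time_from_min(o + starts), durs / 60))
    }
  }
}
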