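test_that("session_interval is half-open [start, start + duration)", {
  iv <- session_interval("2024-06-01 10:00", 1.5)
  expect_equal(format(iv$start, "%H:%M"), "10:00")
  expect_equal(format(iv$end, "%H:%M"), "11:30")

  # crossing midnight
  iv2 <- session_interval("2024-06-01 23:30", 1)
  expect_equal(format(iv2$end, "%Y-%m-%d %H:%M"), "2024-06-02 00:30")

  expect_error(session_interval("2024-06-01 10:00", 0), "positive")
  expect_error(session_interval("2024-06-01 10:00", -1), "positive")
})

test_that("label_timepoint applies the window definitions around one session", {
  ss <- make_sessions("2024-06-01 10:00", 1)
  lab <- function(t) label_timepoint(t, ss)$window_class
  expect_equal(lab("2024-06-01 09:00"), "PRE")
  expect_equal(lab("2024-06-01 10:30"), "DURING")
  expect_equal(lab("2024-06-01 13:59"), "EARLY")
  expect_equal(lab("2024-06-01 20:00"), "LATE")
  expect_equal(lab("2024-06-02 09:00"), "NONEX")
  # boundaries are half-open toward the later window
  expect_equal(lab("2024-06-01 10:00"), "DURING")
  expect_equal(lab("2024-06-01 11:00"), "EARLY")
  expect_equal(lab("2024-06-01 14:00"), "LATE")
  expect_equal(lab("2024-06-02 08:00"), "NONEX")
  expect_equal(lab("2024-06-01 08:00"), "PRE")
  expect_equal(lab("2024-06-01 07:59"), "NONEX")
})

test_that("early recovery of a session outranks the next session's pre-window", {
  ss <- make_sessions(c("2024-06-01 10:00", "2024-06-01 12:30"), 1)
  r <- label_timepoint("2024-06-01 12:00", ss)
  expect_equal(r$window_class, "EARLY")
  expect_equal(r$session_id, "P001-S001")
})

test_that("late recovery is truncated by the next session's pre-window", {
  # A ends 14:00; B starts next day 07:00, so B's pre-window opens 05:00
  ss <- make_sessions(c("2024-06-01 13:00", "2024-06-02 07:00"), 1)
  expect_equal(label_timepoint("2024-06-01 23:00", ss)$window_class, "LATE")
  expect_equal(label_timepoint("2024-06-02 04:59", ss)$window_class, "LATE")
  expect_equal(label_timepoint("2024-06-02 05:00", ss)$window_class, "PRE")
})

test_that("empty session list yields a single NONEX window covering the span", {
  w <- build_window_partition(NULL, "2024-06-01", "2024-06-04")
  expect_equal(nrow(w), 1)
  expect_equal(as.character(w$window_class), "NONEX")
  expect_equal(pg_min(w$end) - pg_min(w$start), 3 * 1440)
})

test_that("a single mid-span session produces the five expected windows", {
  ss <- make_sessions("2024-06-02 10:00", 1.5)
  w <- build_window_partition(ss, "2024-06-01", "2024-06-04")
  cls <- as.character(w$window_class)
  expect_equal(cls, c("NONEX", "PRE", "DURING", "EARLY", "LATE", "NONEX"))
  dur <- pg_min(w$end) - pg_min(w$start)
  expect_equal(sum(dur), 3 * 1440)              # conservation
  expect_equal(dur[cls == "PRE"], 120)
  expect_equal(dur[cls == "DURING"], 90)
  expect_equal(dur[cls == "EARLY"], 180)
  # late: 14:30 -> 08:00 next day
  expect_equal(dur[cls == "LATE"], 17.5 * 60)
})

test_that("overlapping sessions are rejected with the offending pair named", {
  ss <- make_sessions(c("2024-06-01 10:00", "2024-06-01 10:30"), 1)
  expect_error(build_window_partition(ss, "2024-06-01", "2024-06-02"),
               "P001-S001.*P001-S002")
})

test_that("interval partition equals the per-minute labelling on random instances", {
  set.seed(2024)
  n_checked <- 0
  for (rep in 1:20) {
    ss <- random_session_set(sample(1:6, 1))
    w <- build_window_partition(ss, "2024-06-01", "2024-06-04")
    got <- partition_minute_labels(w)
    want <- oracle_minute_labels(ss, "2024-06-01", "2024-06-04")
    expect_identical(got$class, want$class)
    expect_identical(got$session_id, want$session_id)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 20)
})

test_that("partition conserves total time for generated cohorts", {
  co <- generate_cohort(tiny_config(seed = 3))
  w <- cohort_window_partition(co$sessions)
  sp <- study_spans(co$sessions)
  for (pid in sp$participant_id) {
    wp <- w[w$participant_id == pid, ]
    expect_equal(sum(pg_min(wp$end) - pg_min(wp$start)),
                 pg_min(sp$span_end[sp$participant_id == pid]) -
                   pg_min(sp$span_start[sp$participant_id == pid]))
    # windows are sorted, disjoint and contiguous
    expect_true(all(pg_min(wp$start)[-1] == pg_min(wp$end)[-nrow(wp)]))
  }
})

test_that("shrinking the gap to the next session never lengthens LATE", {
  late_minutes <- function(b_start) {
    ss <- make_sessions(c("2024-06-01 10:00", b_start), 1)
    w <- build_window_partition(ss, "2024-06-01", "2024-06-03")
    sel <- w$window_class == "LATE" & !is.na(w$session_id) &
      w$session_id == "P001-S001"
    sum(pg_min(w$end)[sel] - pg_min(w$start)[sel])
  }
  starts <- sprintf("2024-06-02 %02d:00", c(12, 9, 6, 3, 0))
  lens <- vapply(starts, late_minutes, numeric(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("morning cutoff rolls to the next day when early recovery ends after it", {
  # session 05:00-06:00: early recovery ends 09:00 (after 08:00), so late
  # recovery runs to 08:00 the following day
  ss <- make_sessions("2024-06-02 05:00", 1)
  w <- build_window_partition(ss, "2024-06-01", "2024-06-04")
  late <- w[w$window_class == "LATE", ]
  expect_equal(format(late$start, "%H:%M"), "09:00")
  expect_equal(format(late$end, "%Y-%m-%d %H:%M"), "2024-06-03 08:00")
})
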