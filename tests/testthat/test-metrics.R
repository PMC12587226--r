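test_that("band_of implements the consensus thresholds and boundaries", {
  expect_equal(as.character(band_of(c(53, 54, 70, 180, 181, 250, 251, 400, 40))),
               c("<54", "54-69", "70-180", "70-180", "181-250", "181-250",
                 ">250", ">250", "<54"))
  expect_equal(as.character(band_of(69)), "54-69")
  expect_error(band_of(39), "40, 400")
  expect_error(band_of(401), "40, 400")
  expect_error(band_of(NA_real_), "40, 400")
})

test_that("a constant in-range trace gives 100% TIR in every populated class", {
  ss <- make_sessions("2024-06-02 10:00", 1)
  w <- cohort_window_partition(ss, buffer_days = 1)
  sp <- study_spans(ss, buffer_days = 1)
  grid <- seq(pg_min(sp$span_start), pg_min(sp$span_end) - 1, by = 5)
  tr <- data.frame(participant_id = "P001",
                   timestamp = pg_time_from_min(grid),
                   glucose_mg_dl = 100L)
  m <- compute_window_metrics(tr, w)
  pop <- m$n_readings > 0
  expect_true(all(m$tir[pop] == 100))
  expect_true(all(m$tbr_total[pop] == 0))
  expect_true(all(is.na(m$tir[!pop])))
  expect_equal(attr(m, "n_excluded"), 0)
})

test_that("a hand-tallied trace straddling the PRE/DURING boundary matches", {
  ss <- make_sessions("2024-06-02 10:00", 1)
  w <- cohort_window_partition(ss, buffer_days = 1)
  # 12 readings every 5 min from 09:40: 4 in PRE (09:40-09:55),
  # 8 in DURING (10:00-10:35)
  grid <- pg_min(pg_time("2024-06-02 09:40")) + 5 * (0:11)
  glu <- c(65L, 100L, 100L, 200L,   # PRE: 1 low, 2 in-range, 1 high
           rep(c(50L, 100L), each = 4)) # DURING: 4 very low, 4 in-range
  tr <- data.frame(participant_id = "P001",
                   timestamp = pg_time_from_min(grid), glucose_mg_dl = glu)
  m <- compute_window_metrics(tr, w)
  pre <- m[m$window_class == "PRE", ]
  dur <- m[m$window_class == "DURING", ]
  expect_equal(pre$n_readings, 4)
  expect_equal(dur$n_readings, 8)
  expect_equal(pre$pct_54_69, 25)
  expect_equal(pre$pct_70_180, 50)
  expect_equal(pre$pct_181_250, 25)
  expect_equal(dur$pct_lt54, 50)
  expect_equal(dur$pct_70_180, 50)
  expect_equal(dur$tbr_total, 50)
})

test_that("band percentages sum to 100 and counts reconcile, with exclusions warned", {
  co <- generate_cohort(tiny_config(seed = 8))
  w <- cohort_window_partition(co$sessions)
  tr <- synthesize_traces(co$config, co$sessions, w)
  # push a few readings outside every span
  stray <- data.frame(participant_id = "P001",
                      timestamp = pg_time("1999-01-01 00:00") + (0:2) * 300,
                      glucose_mg_dl = 100L)
  expect_warning(m <- compute_window_metrics(rbind(tr, stray), w),
                 "3 readings")
  pop <- m$n_readings > 0
  sums <- rowSums(m[pop, c("pct_lt54", "pct_54_69", "pct_70_180",
                           "pct_181_250", "pct_gt250")])
  expect_true(all(abs(sums - 100) < 1e-6))
  expect_equal(sum(m$n_readings) + attr(m, "n_excluded"), nrow(tr) + 3)
})

test_that("tbr_total equals the direct share of readings below 70", {
  co <- generate_cohort(tiny_config(seed = 9))
  w <- cohort_window_partition(co$sessions)
  tr <- synthesize_traces(co$config, co$sessions, w)
  m <- compute_window_metrics(tr, w)
  # independent route: label readings by window class, count < 70 directly
  for (cl in levels(m$window_class)) {
    wc <- w[w$window_class == cl, ]
    sel <- rep(FALSE, nrow(tr))
    for (i in seq_len(nrow(wc))) {
      sel <- sel | (tr$participant_id == wc$participant_id[i] &
                      pg_min(tr$timestamp) >= pg_min(wc$start[i]) &
                      pg_min(tr$timestamp) < pg_min(wc$end[i]))
    }
    if (!any(sel)) next
    expect_equal(m$tbr_total[m$window_class == cl],
                 100 * mean(tr$glucose_mg_dl[sel] < 70),
                 tolerance = 1e-9)
    expect_equal(m$n_readings[m$window_class == cl], sum(sel))
  }
})

test_that("pooled percentages equal the reading-weighted mean of per-participant ones", {
  co <- generate_cohort(tiny_config(seed = 10))
  w <- cohort_window_partition(co$sessions)
  tr <- synthesize_traces(co$config, co$sessions, w)
  pooled <- compute_window_metrics(tr, w)
  per_part <- lapply(split(seq_len(nrow(tr)), tr$participant_id), function(ix) {
    compute_window_metrics(tr[ix, ], w[w$participant_id ==
                                         tr$participant_id[ix[1]], ])
  })
  for (cl in levels(pooled$window_class)) {
    ns <- vapply(per_part, function(m) m$n_readings[m$window_class == cl],
                 numeric(1))
    ps <- vapply(per_part, function(m) m$pct_lt54[m$window_class == cl],
                 numeric(1))
    if (sum(ns) == 0) next
    expect_equal(pooled$pct_lt54[pooled$window_class == cl],
                 sum(ps * ns, na.rm = TRUE) / sum(ns), tolerance = 1e-9)
  }
})

test_that("participant-weighted pooling averages participants equally", {
  w <- rbind(
    data.frame(participant_id = "A", window_class = factor("DURING"),
               start = pg_time("2024-06-01 10:00"),
               end = pg_time("2024-06-01 11:00"), session_id = "A-S001"),
    data.frame(participant_id = "B", window_class = factor("DURING"),
               start = pg_time("2024-06-01 10:00"),
               end = pg_time("2024-06-01 11:00"), session_id = "B-S001"))
  # A: 2 readings all low; B: 10 readings none low
  tr <- rbind(
    data.frame(participant_id = "A",
               timestamp = pg_time("2024-06-01 10:00") + c(0, 300),
               glucose_mg_dl = 50L),
    data.frame(participant_id = "B",
               timestamp = pg_time("2024-06-01 10:00") + 300 * (0:9),
               glucose_mg_dl = 100L))
  m_read <- compute_window_metrics(tr, w, pooling = "readings")
  m_part <- compute_window_metrics(tr, w, pooling = "participants")
  expect_equal(m_read$pct_lt54[m_read$window_class == "DURING"], 100 * 2 / 12)
  expect_equal(m_part$pct_lt54[m_part$window_class == "DURING"], 50)
})

test_that("metrics_table writes full precision and rounds the console view", {
  co <- generate_cohort(tiny_config(seed = 11))
  w <- cohort_window_partition(co$sessions)
  tr <- synthesize_traces(co$config, co$sessions, w)
  m <- compute_window_metrics(tr, w)
  f <- tempfile(fileext = ".csv")
  out <- capture.output(metrics_table(m, file = f))
  expect_true(length(out) >= 6)
  back <- read.csv(f)
  expect_equal(back$pct_70_180, m$pct_70_180, tolerance = 1e-12)
  expect_equal(nrow(back), 5)
})
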