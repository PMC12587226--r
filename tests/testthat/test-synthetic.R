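test_that("identical config and seed give byte-identical datasets", {
  cfg <- tiny_config(seed = 5)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$sessions, c2$sessions)
  expect_identical(c1$episodes, c2$episodes)
  expect_identical(c1$traces, c2$traces)
  d1 <- file.path(tempdir(), "pgds1"); d2 <- file.path(tempdir(), "pgds2")
  write_dataset(c1, d1); write_dataset(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("growing the cohort never reshuffles earlier participants", {
  small <- generate_cohort(tiny_config(seed = 6, n_participants = 3L))
  big <- generate_cohort(tiny_config(seed = 6, n_participants = 6L))
  expect_identical(small$sessions,
                   big$sessions[big$sessions$participant_id %in%
                                  c("P001", "P002", "P003"), ])
  expect_identical(small$participants, big$participants[1:3, ])
})

test_that("degenerate configurations behave as stated", {
  # zero hypoglycemia rates -> no episodes anywhere
  zero_hypo <- lapply(default_cohort_config()$hypo_prob_by_type_and_level,
                      function(x) x * 0)
  co <- generate_cohort(tiny_config(seed = 7,
                                    hypo_prob_by_type_and_level = zero_hypo))
  expect_equal(nrow(co$episodes), 0)

  # all-aerobic type distribution
  co2 <- generate_cohort(tiny_config(
    seed = 7, activity_type_probs = c(aerobic = 1, anaerobic = 0, mixed = 0)))
  expect_true(all(co2$sessions$activity_type == "aerobic"))

  # degenerate occupancy: every reading lands in 70-180
  occ1 <- lapply(default_cohort_config()$band_occupancy_by_window, function(x) {
    y <- x * 0; y[3] <- 1; y
  })
  cfg3 <- tiny_config(seed = 7, band_occupancy_by_window = occ1)
  co3 <- generate_cohort(cfg3)
  w3 <- cohort_window_partition(co3$sessions)
  tr3 <- synthesize_traces(cfg3, co3$sessions, w3)
  expect_true(all(tr3$glucose_mg_dl >= 70 & tr3$glucose_mg_dl <= 180))

  # full session-level missingness removes every during-window reading
  cfg4 <- tiny_config(seed = 7, cgm_missing_session_prob = 1)
  co4 <- generate_cohort(cfg4)
  w4 <- cohort_window_partition(co4$sessions)
  tr4 <- synthesize_traces(cfg4, co4$sessions, w4)
  m4 <- compute_window_metrics(tr4, w4)
  expect_equal(m4$n_readings[m4$window_class == "DURING"], 0)
  expect_equal(m4$n_readings[m4$window_class == "PRE"], 0)
})

test_that("readings sit on the 5-minute grid inside each participant's span", {
  cfg <- tiny_config(seed = 12)
  co <- generate_cohort(cfg)
  w <- cohort_window_partition(co$sessions)
  tr <- synthesize_traces(cfg, co$sessions, w)
  sp <- study_spans(co$sessions)
  for (pid in sp$participant_id) {
    tm <- pg_min(tr$timestamp[tr$participant_id == pid])
    a <- pg_min(sp$span_start[sp$participant_id == pid])
    b <- pg_min(sp$span_end[sp$participant_id == pid])
    expect_true(all(tm >= a & tm < b))
    expect_true(all((tm - a) %% 5 == 0))
    expect_true(all(diff(tm) > 0))
  }
  expect_true(all(tr$glucose_mg_dl >= 40 & tr$glucose_mg_dl <= 400))
})

test_that("session logbook marginals converge to the configured probabilities", {
  # moderately large logbook-only cohort; 3-SE bands at the realized counts
  cfg <- default_cohort_config(seed = 31, n_participants = 150L)
  co <- generate_cohort(cfg)
  n <- nrow(co$sessions)
  se <- function(p, m = n) sqrt(p * (1 - p) / m)

  p_aer <- mean(co$sessions$activity_type == "aerobic")
  expect_lt(abs(p_aer - cfg$activity_type_probs[["aerobic"]]),
            3 * se(cfg$activity_type_probs[["aerobic"]]))

  p_hypo <- mean(co$sessions$session_id %in% co$episodes$session_id)
  marg <- sum(vapply(names(cfg$activity_type_probs), function(ty)
    cfg$activity_type_probs[[ty]] * sum(cfg$hypo_prob_by_type_and_level[[ty]]),
    numeric(1)))
  # allowance: cluster heterogeneity inflates the SE beyond binomial
  expect_lt(abs(p_hypo - marg), 4 * se(marg))

  prof <- adjustment_profiles(co$sessions, co$carbs)
  has <- !is.na(prof$temp_target_category)
  p_none <- mean(prof$temp_target_category[has] == "none")
  expect_lt(abs(p_none - cfg$temp_target_category_probs[["none"]]),
            3 * se(cfg$temp_target_category_probs[["none"]], sum(has)))
  p_cb <- mean(prof$n_intakes_before > 0)
  expect_lt(abs(p_cb - cfg$carb_before_prob), 3 * se(cfg$carb_before_prob))
  p_miss <- mean(!has)
  expect_lt(abs(p_miss - cfg$adjustment_missing_prob),
            3 * se(cfg$adjustment_missing_prob))
})

test_that("band occupancy of generated readings matches the configured stationary law", {
  cfg <- tiny_config(seed = 13, n_participants = 10L)
  co <- generate_cohort(cfg)
  w <- cohort_window_partition(co$sessions)
  tr <- synthesize_traces(cfg, co$sessions, w)
  m <- compute_window_metrics(tr, w)
  infl <- sqrt((1 + cfg$cgm_persistence) / (1 - cfg$cgm_persistence))
  for (cl in names(cfg$band_occupancy_by_window)) {
    occ <- cfg$band_occupancy_by_window[[cl]]
    row <- m[m$window_class == cl, ]
    if (row$n_readings == 0) next
    got <- as.numeric(row[c("pct_lt54", "pct_54_69", "pct_70_180",
                            "pct_181_250", "pct_gt250")]) / 100
    tol <- 3 * infl * sqrt(occ * (1 - occ) / row$n_readings)
    expect_true(all(abs(got - occ) < pmax(tol, 1e-12)),
                info = sprintf("class %s", cl))
  }
})

test_that("datasets round-trip losslessly through the CSV writers", {
  co <- simulate_cohort(tiny_config(seed = 14, n_participants = 3L))
  d <- file.path(tempdir(), "pg_roundtrip")
  write_dataset(co, d)
  back <- read_dataset(d)
  expect_equal(back$participants, co$participants)
  expect_equal(back$sessions, co$sessions)
  ep <- co$episodes[setdiff(names(co$episodes), c("level", "level_imputed"))]
  expect_equal(back$episodes[names(ep)], ep)
  expect_equal(back$carbs, co$carbs)
  expect_equal(back$traces, co$traces)
  # row-count bookkeeping: cgm.csv rows equal generated readings
  expect_equal(length(readLines(file.path(d, "cgm.csv"))) - 1, nrow(co$traces))
  unlink(d, recursive = TRUE)
})

test_that("an empty cohort writes header-only files", {
  co <- structure(list(participants = generate_cohort(tiny_config(1))$participants[0, ],
                       sessions = periglyc:::.empty_sessions(),
                       episodes = periglyc:::.empty_episodes(),
                       carbs = periglyc:::.empty_carbs()),
                  class = "pg_cohort")
  d <- file.path(tempdir(), "pg_empty")
  write_dataset(co, d)
  for (f in c("participants.csv", "sessions.csv", "episodes.csv", "carbs.csv")) {
    expect_equal(length(readLines(file.path(d, f))), 1)
  }
  back <- read_dataset(d)
  expect_equal(nrow(back$sessions), 0)
  unlink(d, recursive = TRUE)
})

test_that("session counts track the configured weekly rate", {
  cfg <- default_cohort_config(seed = 15)
  co <- generate_cohort(cfg)
  expected <- cfg$n_participants * mean(cfg$sessions_per_week_range) *
    cfg$study_days / 7
  expect_lt(abs(nrow(co$sessions) - expected) / expected, 0.10)
  # start times between 07:00 and 21:00 local
  mins <- pg_min(co$sessions$start) %% 1440
  expect_true(all(mins >= 7 * 60 & mins <= 21 * 60))
  expect_true(all(co$sessions$duration_hours >=
                    cfg$session_duration_hours$min))
})
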