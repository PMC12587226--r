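# Seeded synthetic cohort generator: participants, session logbooks,
# episodes, carbohydrate intakes.
#
# Reproducibility contract: one master seed; every participant draws from
# substreams derived with derive_seed(master, stream, participant_index), so
# enlarging the cohort never reshuffles earlier participants.
#
# Session-level hypoglycemia is drawn from a logistic model
#   logit P(hypo_ij) = mu_type(ij) + b_i + gamma' f_ij
# with participant random intercept b_i ~ N(0, sigma^2) and deviation flags
# f_ij. The type-specific intercepts mu_type are attenuation-corrected by
# numeric integration so that, at gamma = 0, the marginal session rate equals
# the configured per-type probability exactly. Given a hypoglycemic session,
# the episode is level 2 with probability
#   plogis( nu_type + level2_share_sd * w_i ),  w_i ~ N(0,1) independent,
# nu_type attenuation-corrected the same way so the marginal level-2 share
# matches the configured level1/level2 split. The second, independent
# participant effect captures stable inter-individual differences in
# hypoglycemia depth (and lets participant-level level-2 prevalence be
# calibrated independently of the session-level rate).

PG_TYPES <- c("aerobic", "anaerobic", "mixed")
PG_BORG <- c("nothing", "low", "moderate", "high")
PG_BRANDS <- c("Medtronic", "Tandem", "Ypsomed")

#' Generate a synthetic cohort of participants and session logbooks
#'
#' @param config a [default_cohort_config()] object.
#' @return list of class `pg_cohort` with data.frames `participants`,
#'   `sessions`, `episodes`, `carbs` and the `config`.
#' @export
generate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  master <- cfg$seed
  origin_min <- pg_min(pg_time(cfg$study_start))

  # conditional per-type any-hypo intercepts preserving configured marginals
  p_any <- vapply(PG_TYPES, function(ty) sum(cfg$hypo_prob_by_type_and_level[[ty]]),
                  numeric(1))
  share2 <- vapply(PG_TYPES, function(ty) {
    p <- cfg$hypo_prob_by_type_and_level[[ty]]
    if (sum(p) > 0) p[["level2"]] / sum(p) else 0
  }, numeric(1))
  safe_logit <- function(p, sigma) {
    out <- rep(-Inf, length(p))
    pos <- p > 0
    if (any(pos)) out[pos] <- marginal_logit(p[pos], sigma)
    out
  }
  mu_type <- safe_logit(p_any, cfg$random_intercept_sd)
  names(mu_type) <- PG_TYPES
  # level-2 share intercepts on the logit scale (share exactly 0 or 1 kept
  # degenerate)
  nu_type <- ifelse(share2 >= 1, Inf, safe_logit(share2, cfg$level2_share_sd))
  names(nu_type) <- PG_TYPES

  parts <- vector("list", cfg$n_participants)
  sess <- vector("list", cfg$n_participants)
  epis <- vector("list", cfg$n_participants)
  carbs <- vector("list", cfg$n_participants)

  for (k in seq_len(cfg$n_participants)) {
    pid <- sprintf("P%03d", k)

    set.seed(derive_seed(master, "profile", k))
    brand <- sample(PG_BRANDS, 1, prob = cfg$pump_brand_probs)
    b_i <- rnorm(1, 0, cfg$random_intercept_sd)
    w_i <- rnorm(1)
    parts[[k]] <- data.frame(participant_id = pid, pump_brand = brand,
                             random_intercept = b_i,
                             level2_share_effect = cfg$level2_share_sd * w_i,
                             stringsAsFactors = FALSE)

    set.seed(derive_seed(master, "sessions", k))
    sk <- .draw_sessions(cfg, pid, origin_min)
    if (nrow(sk) == 0) { sess[[k]] <- sk; next }

    set.seed(derive_seed(master, "logbook", k))
    lb <- .draw_logbook(cfg, sk, b_i, cfg$level2_share_sd * w_i,
                        mu_type, nu_type)
    sess[[k]] <- lb$sessions
    epis[[k]] <- lb$episodes
    carbs[[k]] <- lb$carbs
  }

  out <- list(
    participants = do.call(rbind, parts),
    sessions = do.call(rbind, sess),
    episodes = .rbind_or_empty(epis, .empty_episodes()),
    carbs = .rbind_or_empty(carbs, .empty_carbs()),
    config = cfg
  )
  rownames(out$sessions) <- rownames(out$participants) <- NULL
  rownames(out$episodes) <- rownames(out$carbs) <- NULL
  class(out) <- "pg_cohort"
  out
}

.rbind_or_empty <- function(lst, empty) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst)) empty else do.call(rbind, lst)
}

.empty_episodes <- function() {
  data.frame(session_id = character(), participant_id = character(),
             phase = character(), min_glucose = numeric(), level = integer(),
             symptom_class = character(), detection = character(),
             interruption = character(), stringsAsFactors = FALSE)
}

.empty_carbs <- function() {
  data.frame(session_id = character(), participant_id = character(),
             when = character(), offset_min = numeric(), grams = numeric(),
             stringsAsFactors = FALSE)
}

# one participant's session scaffold: timing, type, intensity, adjustments
.draw_sessions <- function(cfg, pid, origin_min) {
  weeks <- ceiling(cfg$study_days / 7)
  lo <- cfg$sessions_per_week_range[1]; hi <- cfg$sessions_per_week_range[2]
  days <- integer(0)
  for (w in seq_len(weeks)) {
    n_w <- if (lo == hi) lo else sample(lo:hi, 1)
    avail <- intersect((w - 1) * 7 + 0:6, 0:(cfg$study_days - 1))
    if (!length(avail) || n_w == 0) next
    # partial final week: binomial thinning keeps the weekly rate constant
    if (length(avail) < 7) n_w <- rbinom(1, n_w, length(avail) / 7)
    if (n_w == 0) next
    picked <- avail[sample.int(length(avail), min(n_w, length(avail)))]
    days <- c(days, sort(picked))
  }
  n <- length(days)
  if (n == 0) return(.empty_sessions())
  start_min <- origin_min + days * 1440 +
    floor(runif(n, 7 * 60, 21 * 60 + 1))
  dd <- cfg$session_duration_hours
  dmax <- if (is.null(dd$max)) 8 else dd$max
  dur_h <- round(rtruncnorm(n, dd$mean, dd$sd, dd$min, dmax) * 60) / 60
  ty <- sample(PG_TYPES, n, replace = TRUE, prob = cfg$activity_type_probs)
  borg <- sample(PG_BORG, n, replace = TRUE, prob = cfg$borg_category_probs)

  adj_missing <- runif(n) < cfg$adjustment_missing_prob
  ttcat <- sample(PG_TT_CATEGORIES, n, replace = TRUE,
                  prob = cfg$temp_target_category_probs)
  dur_min <- round(dur_h * 60)
  tt_off <- rep(NA_real_, n)
  ge <- ttcat == "activated_ge_1h_before"
  tt_off[ge] <- -floor(runif(sum(ge), 60, 121))
  lt <- ttcat == "activated_lt_1h_or_during"
  tt_off[lt] <- floor(runif(sum(lt), -59, dur_min[lt] + 1))

  data.frame(
    session_id = sprintf("%s-S%03d", pid, seq_len(n)),
    participant_id = pid,
    start = pg_time_from_min(start_min),
    duration_hours = dur_h,
    activity_type = ty,
    borg_category = borg,
    temp_target_offset_min = tt_off,
    adjustment_missing = adj_missing,
    stringsAsFactors = FALSE
  )
}

.empty_sessions <- function() {
  data.frame(session_id = character(), participant_id = character(),
             start = pg_time_from_min(numeric(0)), duration_hours = numeric(),
             activity_type = character(), borg_category = character(),
             temp_target_offset_min = numeric(), adjustment_missing = logical(),
             stringsAsFactors = FALSE)
}

# carbohydrate intakes, deviation flags, and the hypoglycemia outcome for one
# participant's sessions
.draw_logbook <- function(cfg, sk, b_i, u_i, mu_type, nu_type) {
  n <- nrow(sk)
  dur_min <- round(sk$duration_hours * 60)

  # carbohydrate intakes: one pre-exercise intake, 1-3 during-exercise events
  cb <- runif(n) < cfg$carb_before_prob
  carbs_b <- if (any(cb)) {
    data.frame(session_id = sk$session_id[cb],
               participant_id = sk$participant_id[cb],
               when = "before",
               offset_min = floor(runif(sum(cb), 1, 121)),
               grams = pmax(1, round(rlnorm(sum(cb),
                                            cfg$carb_before_grams$meanlog,
                                            cfg$carb_before_grams$sdlog))),
               stringsAsFactors = FALSE)
  } else NULL
  cd <- runif(n) < cfg$carb_during_prob
  carbs_d <- NULL
  if (any(cd)) {
    idx <- which(cd)
    nev <- sample(as.integer(names(cfg$carb_during_n_probs)), length(idx),
                  replace = TRUE, prob = cfg$carb_during_n_probs)
    rows <- rep(idx, nev)
    eg <- cfg$carb_during_event_grams
    carbs_d <- data.frame(session_id = sk$session_id[rows],
                          participant_id = sk$participant_id[rows],
                          when = "during",
                          offset_min = floor(runif(length(rows)) *
                                               (dur_min[rows] + 1)),
                          grams = pmax(1, round(rlnorm(length(rows),
                                                       eg$meanlog, eg$sdlog))),
                          stringsAsFactors = FALSE)
  }
  carbs <- if (is.null(carbs_b) && is.null(carbs_d)) .empty_carbs() else
    rbind(carbs_b, carbs_d)

  # flags from the *true* adjustments (recording missingness only affects the
  # observed AdjustmentProfile, not the data-generating mechanism)
  prof <- adjustment_profiles(sk[, setdiff(names(sk), "adjustment_missing")],
                              carbs)
  flags <- cbind(
    late_or_no_temp_target = prof$late_or_no_temp_target,
    snack_within_1h_before = prof$snack_within_1h_before,
    single_intake_gt20g_during = prof$single_intake_gt20g_during
  )

  eta <- mu_type[sk$activity_type] + b_i +
    as.numeric(flags %*% cfg$deviation_effect_log_odds)
  p <- ifelse(is.infinite(eta) & eta < 0, 0, plogis(eta))
  hypo <- runif(n) < p

  episodes <- NULL
  if (any(hypo)) {
    hi <- which(hypo)
    m <- length(hi)
    p2 <- plogis(nu_type[sk$activity_type[hi]] + u_i)
    lev <- ifelse(runif(m) < p2, 2L, 1L)
    sympt <- sample(PG_SYMPTOMS, m, replace = TRUE,
                    prob = cfg$symptom_class_probs)
    detection <- ifelse(sympt == "asymptomatic",
                        sample(c("cgm", "capillary"), m, replace = TRUE),
                        "symptoms")
    ming <- ifelse(lev == 2L, floor(runif(m, 40, 54)), floor(runif(m, 54, 70)))
    drop_g <- lev == 1L & sympt != "asymptomatic" &
      runif(m) < cfg$episode_missing_glucose_prob
    ming[drop_g] <- NA_real_
    episodes <- data.frame(
      session_id = sk$session_id[hi],
      participant_id = sk$participant_id[hi],
      phase = sample(PG_PHASES, m, replace = TRUE,
                     prob = cfg$episode_phase_probs),
      min_glucose = ming,
      level = lev,
      symptom_class = sympt,
      detection = detection,
      interruption = sample(PG_INTERRUPT, m, replace = TRUE,
                            prob = cfg$interruption_probs),
      stringsAsFactors = FALSE
    )
  }
  list(sessions = sk, episodes = episodes, carbs = carbs)
}

#' @export
print.pg_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d sessions, %d episodes, %d carb intakes\n",
              nrow(x$participants), nrow(x$sessions), nrow(x$episodes),
              nrow(x$carbs)))
  invisible(x)
}
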