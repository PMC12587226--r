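# CGM trace synthesis.
#
# Band process: within each labeled window the band of consecutive readings
# follows a stay-or-redraw Markov chain — with probability `cgm_persistence`
# the band of the previous reading is kept, otherwise a fresh band is drawn
# from the window class's configured occupancy. The chain is re-initialized
# from the occupancy at the first reading of every window, so the stationary
# distribution holds exactly for every reading and no occupancy carries over
# across window-class boundaries. Within-band glucose values are uniform
# integers over the band's range, clamped to [40, 400] mg/dL.
#
# Session-level missingness: for a configured fraction of sessions all
# readings in [session start - 2 h, session end + 3 h] are deleted, emulating
# sessions for which no CGM download was available.

PG_BAND_LO <- c(40L, 54L, 70L, 181L, 251L)
PG_BAND_HI <- c(53L, 69L, 180L, 250L, 400L)

#' Synthesize CGM traces for a cohort
#'
#' @param config a [default_cohort_config()] object (the same one used to
#'   generate the cohort).
#' @param sessions cohort session table (used for session-level CGM
#'   missingness).
#' @param windows labeled window partition covering each participant's study
#'   span ([cohort_window_partition()]).
#' @return data.frame with columns `participant_id`, `timestamp` (POSIXct on
#'   a 5-minute grid from each participant's span start), `glucose_mg_dl`
#'   (integer).
#' @export
synthesize_traces <- function(config, sessions, windows) {
  cfg <- validate_cohort_config(config)
  master <- cfg$seed
  occ <- do.call(rbind, cfg$band_occupancy_by_window[PG_CLASSES])
  rho <- cfg$cgm_persistence

  pids <- unique(windows$participant_id)
  out <- vector("list", length(pids))
  for (i in seq_along(pids)) {
    pid <- pids[i]
    w <- windows[windows$participant_id == pid, , drop = FALSE]
    w <- w[order(pg_min(w$start)), , drop = FALSE]
    a <- pg_min(w$start[1]); b <- pg_min(w$end[nrow(w)])
    if (any(pg_min(w$start)[-1] != pg_min(w$end)[-nrow(w)])) {
      stop("windows must form a contiguous partition per participant",
           call. = FALSE)
    }
    grid <- seq(a, b - 1, by = 5)
    pos <- findInterval(grid, pg_min(w$start))
    if (any(pos < 1)) {
      stop("window partition does not cover a requested timestamp",
           call. = FALSE)
    }
    cls <- as.integer(factor(w$window_class[pos], levels = PG_CLASSES))

    # participant index from the id keeps substreams stable however the
    # windows are ordered
    k <- suppressWarnings(as.integer(sub("^\\D*", "", pid)))
    if (is.na(k)) k <- i
    set.seed(derive_seed(master, "cgm", k))
    n <- length(grid)
    # forced redraw at the first reading of each window
    new_window <- c(TRUE, pos[-1] != pos[-n])
    redraw <- new_window | (runif(n) >= rho)
    run_id <- cumsum(redraw)
    run_cls <- cls[redraw]
    u <- runif(length(run_cls))
    cum <- t(apply(occ, 1, cumsum))
    run_band <- integer(length(run_cls))
    for (cl in unique(run_cls)) {
      sel <- run_cls == cl
      run_band[sel] <- findInterval(u[sel], c(0, cum[cl, ]),
                                    rightmost.closed = TRUE)
    }
    run_band[run_band > 5L] <- 5L
    band <- run_band[run_id]
    lo <- PG_BAND_LO[band]; hi <- PG_BAND_HI[band]
    glucose <- lo + floor(runif(n) * (hi - lo + 1))

    # session-level missingness
    ss <- sessions[sessions$participant_id == pid, , drop = FALSE]
    keep <- rep(TRUE, n)
    if (nrow(ss) > 0 && cfg$cgm_missing_session_prob > 0) {
      set.seed(derive_seed(master, "cgm_missing", k))
      drop_sess <- runif(nrow(ss)) < cfg$cgm_missing_session_prob
      if (any(drop_sess)) {
        iv <- session_interval(ss$start[drop_sess],
                               ss$duration_hours[drop_sess])
        for (j in seq_len(sum(drop_sess))) {
          keep[grid >= pg_min(iv$start[j]) - PRE_MIN &
                 grid < pg_min(iv$end[j]) + EARLY_MIN] <- FALSE
        }
      }
    }
    out[[i]] <- data.frame(participant_id = pid,
                           timestamp = pg_time_from_min(grid[keep]),
                           glucose_mg_dl = as.integer(glucose[keep]),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_cohort()],
#' [cohort_window_partition()] and [synthesize_traces()].
#'
#' @param config a [default_cohort_config()] object.
#' @return a `pg_cohort` list with the additional elements `windows` and
#'   `traces`.
#' @export
simulate_cohort <- function(config = default_cohort_config()) {
  cohort <- generate_cohort(config)
  cohort$windows <- cohort_window_partition(cohort$sessions)
  cohort$traces <- synthesize_traces(cohort$config, cohort$sessions,
                                     cohort$windows)
  cohort
}
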