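# Glucose band metrics (TBR / TIR / TAR) pooled per window class.
#
# Band thresholds follow the international consensus CGM targets:
#   <54 | 54-69 | 70-180 | 181-250 | >250  (mg/dL)
# i.e. TBR level 2 is glucose < 54, TBR level 1 is 54-69 (total TBR < 70),
# TIR is 70-180 inclusive, TAR level 1 is (180, 250], TAR level 2 is > 250.

PG_BANDS <- c("<54", "54-69", "70-180", "181-250", ">250")

#' Glucose band of a reading
#'
#' @param glucose numeric glucose values in mg/dL, each in `[40, 400]`.
#' @return factor with levels `<54`, `54-69`, `70-180`, `181-250`, `>250`.
#' @export
band_of <- function(glucose) {
  if (any(!is.finite(glucose)) || any(glucose < 40 | glucose > 400)) {
    stop("glucose values must lie in [40, 400] mg/dL", call. = FALSE)
  }
  idx <- 1L + (glucose >= 54) + (glucose >= 70) + (glucose > 180) + (glucose > 250)
  factor(PG_BANDS[idx], levels = PG_BANDS)
}

# assign each reading to the window containing its timestamp.
# Returns integer index into `windows` rows (NA if outside the span).
.assign_windows <- function(traces, windows) {
  idx_all <- rep(NA_integer_, nrow(traces))
  worder <- order(windows$participant_id, pg_min(windows$start))
  windows <- windows[worder, , drop = FALSE]
  for (pid in unique(traces$participant_id)) {
    tr <- which(traces$participant_id == pid)
    wi <- which(windows$participant_id == pid)
    if (!length(wi)) next
    tm <- pg_min(traces$timestamp[tr])
    starts <- pg_min(windows$start[wi])
    ends <- pg_min(windows$end[wi])
    pos <- findInterval(tm, starts)
    ok <- pos >= 1 & pos <= length(wi)
    ok[ok] <- tm[ok] < ends[pos[ok]]
    idx_all[tr[ok]] <- worder[wi[pos[ok]]]
  }
  idx_all
}

#' Pooled per-window-class glucose band metrics
#'
#' Assigns every CGM reading to the unique labeled window containing its
#' timestamp and pools band percentages over all readings of each window
#' class. Pooling is reading-weighted by default (percentage of all reading
#' time of that class, across participants and sessions); the alternative
#' averages per-participant percentages with equal participant weight.
#'
#' @param traces data.frame with columns `participant_id`, `timestamp`
#'   (POSIXct), `glucose_mg_dl`.
#' @param windows labeled partition as returned by
#'   [cohort_window_partition()].
#' @param pooling `"readings"` (default) or `"participants"`.
#' @return data.frame with one row per window class: `window_class`,
#'   `n_readings`, `hours`, `pct_lt54`, `pct_54_69`, `pct_70_180`,
#'   `pct_181_250`, `pct_gt250`, `tbr_total`, `tir`, `tar_total`. Percentages
#'   are `NA` for classes with zero readings. The number of readings falling
#'   outside any window is attached as attribute `n_excluded` (with a warning
#'   when positive).
#' @export
compute_window_metrics <- function(traces, windows,
                                   pooling = c("readings", "participants")) {
  pooling <- match.arg(pooling)
  stopifnot(all(c("participant_id", "timestamp", "glucose_mg_dl") %in% names(traces)))
  idx <- .assign_windows(traces, windows)
  n_excl <- sum(is.na(idx))
  if (n_excl > 0) {
    warning(sprintf("%d readings fall outside every labeled window and were excluded",
                    n_excl), call. = FALSE)
  }
  keep <- !is.na(idx)
  cls <- factor(windows$window_class[idx[keep]], levels = PG_CLASSES)
  band <- band_of(traces$glucose_mg_dl[keep])

  if (pooling == "readings") {
    tab <- table(cls, band)
    n <- rowSums(tab)
    pct <- 100 * sweep(tab, 1, pmax(n, 1), "/")
    pct[n == 0, ] <- NA_real_
  } else {
    pid <- traces$participant_id[keep]
    tab3 <- table(pid, cls, band)
    npc <- apply(tab3, c(1, 2), sum)
    prop <- array(NA_real_, dim(tab3), dimnames = dimnames(tab3))
    for (b in seq_len(dim(tab3)[3])) {
      prop[, , b] <- ifelse(npc > 0, tab3[, , b] / npc, NA_real_)
    }
    pct <- 100 * apply(prop, c(2, 3), mean, na.rm = TRUE)
    n <- colSums(npc)
    pct[n == 0, ] <- NA_real_
  }

  out <- data.frame(
    window_class = factor(PG_CLASSES, levels = PG_CLASSES),
    n_readings = as.integer(n[PG_CLASSES]),
    hours = as.numeric(n[PG_CLASSES]) * 5 / 60,
    pct_lt54 = pct[PG_CLASSES, "<54"],
    pct_54_69 = pct[PG_CLASSES, "54-69"],
    pct_70_180 = pct[PG_CLASSES, "70-180"],
    pct_181_250 = pct[PG_CLASSES, "181-250"],
    pct_gt250 = pct[PG_CLASSES, ">250"],
    row.names = NULL
  )
  out$tbr_total <- out$pct_lt54 + out$pct_54_69
  out$tir <- out$pct_70_180
  out$tar_total <- out$pct_181_250 + out$pct_gt250
  attr(out, "n_excluded") <- n_excl
  out
}

#' Render a window-metrics table
#'
#' One row per window class with the five band percentages and derived
#' aggregates. The console view rounds percentages to integers; the optional
#' CSV keeps full precision.
#'
#' @param metrics result of [compute_window_metrics()].
#' @param file optional path to write a full-precision CSV.
#' @param quiet suppress console printing.
#' @return the (full-precision) metrics data.frame, invisibly.
#' @export
metrics_table <- function(metrics, file = NULL, quiet = FALSE) {
  if (!is.null(file)) {
    write.csv(metrics, file, row.names = FALSE)
  }
  if (!quiet) {
    disp <- metrics
    pct_cols <- grep("^(pct_|tbr|tir|tar)", names(disp))
    disp[pct_cols] <- lapply(disp[pct_cols], function(x) round(x))
    disp$hours <- round(disp$hours, 1)
    print(disp, row.names = FALSE)
  }
  invisible(metrics)
}
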