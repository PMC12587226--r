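#' @importFrom stats plogis qlogis qnorm pnorm rnorm runif rbinom quantile
#'   median sd optim optimHess uniroot rlnorm
#' @importFrom utils read.csv write.csv head
NULL

# Time is handled as timezone-naive local clock time; internally POSIXct in UTC
# so arithmetic never crosses a DST transition. Minute resolution throughout.
PG_TZ <- "UTC"

#' Parse timestamps in the package's canonical form
#'
#' Accepts `"YYYY-MM-DD HH:MM"` or ISO-8601 `"YYYY-MM-DDTHH:MM:SS"` strings
#' (no timezone suffix) and returns POSIXct at minute resolution.
#'
#' @param x character vector of timestamps, or POSIXct (returned as-is after
#'   flooring to the minute).
#' @return POSIXct vector (UTC-internal, representing naive local time).
#' @export
pg_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(as.POSIXct(floor(as.numeric(x) / 60) * 60,
                      origin = "1970-01-01", tz = PG_TZ))
  }
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = PG_TZ,
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  pg_time_from_min(floor(as.numeric(out) / 60))
}

#' Convert between POSIXct and epoch minutes
#'
#' The package does all interval arithmetic on integer epoch minutes;
#' these helpers convert in both directions.
#'
#' @param t POSIXct vector (or numeric, returned unchanged).
#' @param m numeric vector of minutes since 1970-01-01 00:00.
#' @return `pg_min()`: numeric epoch minutes; `pg_time_from_min()`: POSIXct.
#' @export
pg_min <- function(t) {
  if (inherits(t, "POSIXct")) floor(as.numeric(t) / 60) else as.numeric(t)
}

#' @rdname pg_min
#' @export
pg_time_from_min <- function(m) {
  as.POSIXct(m * 60, origin = "1970-01-01", tz = PG_TZ)
}

#' Format timestamps as ISO-8601 local time without timezone suffix
#'
#' @param t POSIXct vector.
#' @return character vector like `"2024-06-01T10:00:00"`.
#' @export
pg_format_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = PG_TZ)

#' Derive a reproducible substream seed from a master seed
#'
#' Counter-scheme seed derivation: the master seed is folded with a sequence of
#' integer or character keys through a Lehmer-style multiplicative congruential
#' step (modulus 2147483629, multiplier 48271, exact in double precision).
#' Adding participants or streams never reshuffles earlier substreams because
#' each substream's seed depends only on the master seed and its own keys.
#'
#' @param master integer master seed.
#' @param ... integer or character keys identifying the substream
#'   (e.g. `"sessions", participant_index`).
#' @return an integer seed in `[1, 2147483628]`, suitable for [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483629
  x <- (abs(as.numeric(master)) %% m)
  for (k in list(...)) {
    kk <- if (is.character(k)) {
      ints <- utf8ToInt(k)
      sum(ints * seq_along(ints)) %% m
    } else {
      abs(as.numeric(k)) %% m
    }
    x <- (x * 48271 + kk + 1) %% m
  }
  # one extra scrambling step so short key lists are well spread
  x <- (x * 48271 + 1) %% m
  as.integer(x %% 2147483628) + 1L
}

# Truncated-normal draws by inverse-CDF (exact, no rejection loops).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# Gauss-Hermite nodes/weights for E[f(Z)], Z ~ N(0,1): nodes scaled by sqrt(2),
# weights normalized by 1/sqrt(pi).
gh_normal <- function(n) {
  gh <- pracma::gaussHermite(n)
  list(z = gh$x * sqrt(2), w = gh$w / sqrt(pi))
}

# E[plogis(mu + sigma * Z)] by Gauss-Hermite quadrature.
logit_normal_mean <- function(mu, sigma, gh = gh_normal(40)) {
  vapply(mu, function(m) sum(gh$w * plogis(m + sigma * gh$z)), numeric(1))
}

#' Intercept correction for a logit-normal random-intercept model
#'
#' Given a target marginal probability `p` and a random-intercept SD `sigma`,
#' solves for the conditional (subject-level) intercept `mu` such that
#' `E[plogis(mu + sigma * Z)] = p` for `Z ~ N(0, 1)`. Without this correction,
#' adding a random intercept to `qlogis(p)` inflates the marginal event rate
#' for rare events.
#'
#' @param p target marginal probability (vectorized), in (0, 1).
#' @param sigma random-intercept standard deviation, `>= 0`.
#' @return conditional intercepts on the log-odds scale, same length as `p`.
#' @export
marginal_logit <- function(p, sigma) {
  stopifnot(all(p > 0 & p < 1), sigma >= 0)
  if (sigma == 0) return(qlogis(p))
  gh <- gh_normal(40)
  vapply(p, function(pp) {
    uniroot(function(mu) logit_normal_mean(mu, sigma, gh) - pp,
            lower = qlogis(pp) - sigma^2 - 5, upper = qlogis(pp) + 1,
            tol = 1e-10)$root
  }, numeric(1))
}

# FNV-1a 32-bit hash of a character vector, returned as 8-hex-digit string.
# Used to stamp run logs with a config fingerprint. Arithmetic split into
# 16-bit halves so every intermediate stays exact in double precision.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * prime) %% 65536) * 65536 + lo * prime
    h <- h %% 4294967296
  }
  sprintf("%08x", h)
}

# next clock occurrence of `cutoff_min` minutes-past-midnight strictly after
# epoch-minute x (vectorized)
next_clock_after <- function(x, cutoff_min = 480) {
  d <- (cutoff_min - x) %% 1440
  d[d == 0] <- 1440
  x + d
}

# probability-vector validation helper
check_probs <- function(p, name, n = NULL, tol = 1e-9) {
  if (!is.null(n) && length(p) != n) {
    stop(sprintf("config field '%s' must have %d entries", name, n), call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    stop(sprintf("config field '%s' must be finite and nonnegative", name),
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("config field '%s' must sum to 1 (got %.12f)", name, sum(p)),
         call. = FALSE)
  }
  invisible(p)
}
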