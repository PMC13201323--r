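## Shared helpers: circular ordinal-year arithmetic, seed streams, small checks.

#' Signed circular difference between ordinal days
#'
#' Shortest-arc signed difference `a - b` on a circular year of `period` days.
#' Positive means `a` falls later than `b` along the shorter arc.
#'
#' @param a,b ordinal days (numeric, may be vectors).
#' @param period cycle length in days (default 365).
#' @return signed difference in `(-period/2, period/2]` (integer days for
#'   integer input).
#' @export
circ_diff <- function(a, b, period = 365) {
  half <- floor(period / 2)
  ((a - b + half) %% period) - half
}

#' Circular midpoint of two ordinal days
#'
#' Midpoint along the shorter arc from `a` to `b`, rounded half-up to the
#' nearest day and wrapped into `1..period`.
#'
#' @inheritParams circ_diff
#' @return ordinal day in `1..period`.
#' @export
circ_midpoint <- function(a, b, period = 365) {
  m <- a + circ_diff(b, a, period) / 2
  wrap_day(floor(m + 0.5), period)
}

# wrap any integer day onto 1..period
wrap_day <- function(d, period = 365) ((d - 1) %% period) + 1

#' Ordinal day on a fixed 365-day cycle
#'
#' Day-of-year with leap days merged: Feb 29 maps to day 59 (the Feb 28 slot)
#' and later days of leap years shift down by one, so every date lands on
#' 1..365. This keeps multi-year data commensurable on one circular year.
#'
#' @param when Date or POSIXct vector.
#' @return integer ordinal days in 1..365.
#' @export
ordinal_day <- function(when) {
  lt <- as.POSIXlt(when, tz = "UTC")
  yd <- lt$yday + 1L                      # 1-based day of year
  leap <- (lt$year + 1900L) %% 4L == 0L &
    ((lt$year + 1900L) %% 100L != 0L | (lt$year + 1900L) %% 400L == 0L)
  yd[leap & yd == 60L] <- 59L
  yd[leap & yd > 60L] <- yd[leap & yd > 60L] - 1L
  yd
}

# deterministic per-unit seed stream; stays below 2^31
derive_seed <- function(base, i) {
  as.integer((as.numeric(base) * 48271 + 7919 * as.numeric(i)) %% 2147483629)
}

# wrap degrees onto (-180, 180]
wrap180 <- function(d) {
  r <- d %% 360
  r[!is.na(r) & r > 180] <- r[!is.na(r) & r > 180] - 360
  r
}

stop_ecoseasons <- function(msg, class) {
  stop(structure(class = c(class, "ecoseasons_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
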