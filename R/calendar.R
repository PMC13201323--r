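## Season calendars: ordered space-use states with transition dates on the
## circular 365-day ordinal year. Used both as simulation ground truth and as
## the headline output of the seasonality pipeline.

#' Construct a season calendar
#'
#' States are maximal circular blocks of ordinal days sharing a label; their
#' windows must tile the 365-day circle exactly. Each transition date is the
#' first day of the incoming state.
#'
#' @param states data.frame with `label`, `start_day`, `end_day` (inclusive,
#'   circular: a winter state may have `start_day > end_day`).
#' @param provenance free-form list recording how the calendar was produced
#'   (k, seeds, smoothing window, run length, ...).
#' @return a `season_calendar` with `states`, `transitions`
#'   (`from`, `to`, `day`), `day_state` (length-365 label lookup) and
#'   `provenance`.
#' @export
season_calendar <- function(states, provenance = list()) {
  stopifnot(is.data.frame(states),
            all(c("label", "start_day", "end_day") %in% names(states)))
  lookup <- rep(NA_character_, 365)
  for (s in seq_len(nrow(states))) {
    days <- if (states$start_day[s] <= states$end_day[s]) {
      states$start_day[s]:states$end_day[s]
    } else {
      c(states$start_day[s]:365, 1:states$end_day[s])
    }
    if (any(!is.na(lookup[days]))) {
      stop_ecoseasons("state windows overlap", "invalid_calendar_error")
    }
    lookup[days] <- states$label[s]
  }
  if (anyNA(lookup)) {
    stop_ecoseasons("state windows do not tile the 365-day circle",
                    "invalid_calendar_error")
  }
  ord <- order(wrap_day(states$start_day))
  states <- states[ord, , drop = FALSE]
  rownames(states) <- NULL
  n <- nrow(states)
  transitions <- if (n >= 2) {
    data.frame(from = states$label[c(n, seq_len(n - 1L))],
               to = states$label,
               day = states$start_day,
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), day = integer(0))
  }
  structure(list(states = states, transitions = transitions,
                 day_state = lookup, provenance = provenance),
            class = "season_calendar")
}

#' State label for ordinal days
#'
#' @param calendar a `season_calendar`.
#' @param day ordinal day(s) in 1..365.
#' @return character vector of state labels.
#' @export
state_of_day <- function(calendar, day) {
  stopifnot(inherits(calendar, "season_calendar"))
  calendar$day_state[wrap_day(day)]
}

# "10 Apr" style label for an ordinal day (non-leap reference year)
format_ordinal <- function(day) {
  format(as.Date(day - 1, origin = "2021-01-01"), "%d %b")
}

#' @export
print.season_calendar <- function(x, ...) {
  cat(sprintf("Season calendar: %d state(s)\n", nrow(x$states)))
  for (s in seq_len(nrow(x$states))) {
    cat(sprintf("  %-14s %s - %s\n", x$states$label[s],
                format_ordinal(x$states$start_day[s]),
                format_ordinal(x$states$end_day[s])))
  }
  if (nrow(x$transitions)) {
    cat("Transitions:\n")
    for (t in seq_len(nrow(x$transitions))) {
      cat(sprintf("  %s -> %s on %s (day %d)\n", x$transitions$from[t],
                  x$transitions$to[t], format_ordinal(x$transitions$day[t]),
                  x$transitions$day[t]))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.season_calendar <- function(x, ...) x$states

#' Write a season calendar to JSON
#'
#' @param calendar a `season_calendar`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calendar <- function(calendar, path) {
  jsonlite::write_json(list(states = calendar$states,
                            transitions = calendar$transitions,
                            provenance = calendar$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a season calendar written by [write_calendar()]
#'
#' @param path JSON path.
#' @return a `season_calendar`.
#' @export
read_calendar <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  season_calendar(as.data.frame(j$states), provenance = as.list(j$provenance))
}
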