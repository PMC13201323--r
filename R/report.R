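## Derived quantities and serialization: growing-degree-day series, the
## green-up/snow correlation, cross-population transition offsets, and
## figure-ready CSV/JSON exports with provenance headers.

#' Growing-degree-day series from daily weather
#'
#' Daily GDD increment is `max(0, mean_temp - base_temp)`; accumulation
#' resets every 1 January. The day-over-day change of the accumulation
#' (delta GDD) equals the increment and is the green-up proxy used for
#' seasonal context. The base threshold is exposed directly (a latitude
#' adjusted plant-growth threshold of about 1 C is appropriate for
#' western-Lake-Superior latitudes); any external latitudinal correction is
#' applied by choosing `base_temp`.
#'
#' @param weather data.frame with `date` and `mean_temp` (C), no duplicate
#'   dates. Missing days stay missing; they are never zero-filled.
#' @param base_temp plant-growth threshold in C (default 1.0).
#' @return a `gdd_series` data.frame: `date`, `mean_temp`, `gdd_increment`,
#'   `gdd_accum`, `delta_gdd`; attribute `base_temp`.
#' @export
gdd_series <- function(weather, base_temp = 1.0) {
  stopifnot(all(c("date", "mean_temp") %in% names(weather)))
  if (anyDuplicated(weather$date)) {
    stop_ecoseasons("duplicate dates in weather table", "invalid_config_error")
  }
  w <- weather[order(weather$date), , drop = FALSE]
  inc <- pmax(0, w$mean_temp - base_temp)
  yr <- as.integer(format(w$date, "%Y"))
  accum <- stats::ave(inc, yr, FUN = cumsum)
  out <- data.frame(date = w$date, mean_temp = w$mean_temp,
                    gdd_increment = inc, gdd_accum = accum, delta_gdd = inc)
  attr(out, "base_temp") <- base_temp
  class(out) <- c("gdd_series", "data.frame")
  out
}

#' Correlate green-up with snow depth
#'
#' Pearson correlation of aligned daily delta-GDD and snow-depth values with
#' its t statistic `t = r * sqrt((n - 2) / (1 - r^2))` and two-sided p value.
#'
#' @param gdd numeric delta-GDD vector (or a `gdd_series`, whose `delta_gdd`
#'   is used).
#' @param snow numeric snow-depth vector aligned with `gdd`.
#' @return list with `r`, `t_statistic`, `p`, `n`.
#' @export
correlate_gdd_snow <- function(gdd, snow) {
  if (inherits(gdd, "gdd_series")) gdd <- gdd$delta_gdd
  ok <- !is.na(gdd) & !is.na(snow)
  gdd <- gdd[ok]; snow <- snow[ok]
  n <- length(gdd)
  stopifnot(n >= 3)
  if (stats::sd(gdd) == 0 || stats::sd(snow) == 0) {
    stop_ecoseasons("zero variance in one of the series; correlation undefined",
                    "undefined_correlation_error")
  }
  r <- stats::cor(gdd, snow)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(r = r, t_statistic = t, p = p, n = n)
}

#' Signed transition-date offsets between populations
#'
#' For every pair of populations supplying a dated transition for the same
#' boundary type, the signed circular day difference (shortest arc; positive
#' means population A transitions later than population B). Populations
#' missing a boundary are skipped with a notice.
#'
#' @param transitions data.frame with `population`, `boundary` (e.g.
#'   "summer_to_winter"), and `day` (ordinal) or `date` (Date, converted via
#'   [ordinal_day()]).
#' @return an `offset_table` data.frame: `population_a`, `population_b`,
#'   `boundary`, `offset_days` with antisymmetric rows (both directions).
#' @export
season_offsets <- function(transitions) {
  tr <- transitions
  if (!"day" %in% names(tr)) {
    stopifnot("date" %in% names(tr))
    tr$day <- ordinal_day(as.Date(tr$date))
  }
  out <- list()
  for (b in unique(tr$boundary)) {
    sub <- tr[tr$boundary == b, , drop = FALSE]
    pops <- unique(tr$population)
    have <- pops[pops %in% sub$population]
    missing <- setdiff(pops, have)
    if (length(missing)) {
      message(sprintf("boundary '%s': no transition for %s; rows omitted",
                      b, paste(missing, collapse = ", ")))
    }
    if (length(have) < 2) next
    for (a in have) for (p2 in have) {
      if (a == p2) next
      da <- sub$day[sub$population == a][1]
      db <- sub$day[sub$population == p2][1]
      out[[length(out) + 1L]] <- data.frame(
        population_a = a, population_b = p2, boundary = b,
        offset_days = circ_diff(da, db), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(population_a = character(0), population_b = character(0),
               boundary = character(0), offset_days = numeric(0))
  class(res) <- c("offset_table", "data.frame")
  res
}

# provenance header lines for CSV exports
provenance_header <- function(provenance) {
  stamp <- c(package = as.character(utils::packageVersion("ecoseasons")),
             unlist(provenance))
  paste0("# ", names(stamp), ": ", stamp)
}

write_csv_with_header <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(provenance), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Export pipeline artifacts
#'
#' Writes whatever stage outputs are supplied: the season calendar as JSON, a
#' per-ordinal-day state/delta-GDD calendar CSV, the PCA loadings CSV, and
#' the pooled RSF coefficient CSV. Every CSV starts with `#`-prefixed
#' provenance lines (package version, seeds, configuration); re-export with
#' identical inputs is byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param calendar optional `season_calendar` (or named list of them, one per
#'   population).
#' @param gdd optional `gdd_series` to merge into the calendar CSV.
#' @param pca optional `pca_summary`.
#' @param pooled optional `population_rsf` (or named list of them).
#' @param provenance named list recorded in every header.
#' @return character vector of files written, invisibly.
#' @export
export_reports <- function(out_dir, calendar = NULL, gdd = NULL, pca = NULL,
                           pooled = NULL, provenance = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  jsonlite::write_json(list(provenance = c(list(
    package = as.character(utils::packageVersion("ecoseasons"))), provenance)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  written <- c(written, file.path(out_dir, "provenance.json"))

  cals <- if (inherits(calendar, "season_calendar")) list(population = calendar)
          else calendar
  if (!is.null(cals)) {
    for (nm in names(cals)) {
      f <- file.path(out_dir, sprintf("calendar_%s.json", nm))
      write_calendar(cals[[nm]], f)
      written <- c(written, f)
    }
    daily <- do.call(rbind, lapply(names(cals), function(nm) {
      data.frame(population = nm, ordinal_day = 1:365,
                 state = state_of_day(cals[[nm]], 1:365))
    }))
    if (!is.null(gdd)) {
      byday <- tapply(gdd$delta_gdd, ordinal_day(gdd$date), mean, na.rm = TRUE)
      daily$delta_gdd <- as.numeric(byday[as.character(daily$ordinal_day)])
    }
    f <- file.path(out_dir, "state_calendar.csv")
    write_csv_with_header(daily, f, provenance)
    written <- c(written, f)
  }
  if (!is.null(pca)) {
    ld <- data.frame(covariate = rownames(pca$loadings),
                     component_1 = pca$loadings[, 1],
                     component_2 = pca$loadings[, 2])
    f <- file.path(out_dir, "pca_loadings.csv")
    write_csv_with_header(ld, f, c(provenance, list(
      pct_variance_1 = pca$pct_variance[1],
      pct_variance_2 = pca$pct_variance[2])))
    written <- c(written, f)
  }
  pools <- if (inherits(pooled, "population_rsf")) list(population = pooled)
           else pooled
  if (!is.null(pools)) {
    tab <- do.call(rbind, lapply(names(pools), function(nm) {
      cbind(population = nm, pools[[nm]]$table)
    }))
    f <- file.path(out_dir, "pooled_rsf.csv")
    write_csv_with_header(tab, f, provenance)
    written <- c(written, f)
  }
  invisible(written)
}
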