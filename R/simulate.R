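## Regime-switching, habitat-weighted correlated random walk simulator.
## Regimes play the role of population-level seasons: every individual shares
## the same regime day-windows, so the true season calendar is known and
## downstream recovery can be scored against it.

#' Movement/selection regime specification
#'
#' One behavioral regime: a gamma step-length law, a von Mises turning-angle
#' law, log-scale selection weights per land-cover class and per continuous
#' layer, and the (circular) ordinal-day window in which the regime holds.
#'
#' @param name regime label.
#' @param step_scale gamma scale of the per-fix step length, meters (> 0).
#' @param step_shape gamma shape (> 0); mean step is `step_shape * step_scale`.
#' @param angular_concentration von Mises concentration of turning angles
#'   (>= 0; 0 = uniform turning, larger = straighter paths).
#' @param habitat_weights named numeric, one log-scale selection weight per
#'   land-cover class (missing classes default to 0).
#' @param slope_w,northness_w,dist_lake_w,dist_road_w selection slopes for the
#'   continuous layers (per unit of the layer).
#' @param start_day,end_day inclusive ordinal-day window (circular; a winter
#'   regime may have `start_day > end_day`).
#' @return a `regime_spec` list.
#' @export
regime_spec <- function(name, step_scale, step_shape = 1.5,
                        angular_concentration = 0.5,
                        habitat_weights = numeric(0),
                        slope_w = 0, northness_w = 0,
                        dist_lake_w = 0, dist_road_w = 0,
                        start_day = 1, end_day = 365) {
  if (step_scale <= 0 || step_shape <= 0 || angular_concentration < 0) {
    stop_ecoseasons("step_scale/step_shape must be > 0 and angular_concentration >= 0",
                    "invalid_config_error")
  }
  hw <- stats::setNames(rep(0, length(LAND_COVER_CLASSES)), LAND_COVER_CLASSES)
  if (length(habitat_weights)) {
    stopifnot(all(names(habitat_weights) %in% LAND_COVER_CLASSES))
    hw[names(habitat_weights)] <- habitat_weights
  }
  structure(list(name = name, step_scale = step_scale, step_shape = step_shape,
                 angular_concentration = angular_concentration,
                 habitat_weights = hw, slope_w = slope_w,
                 northness_w = northness_w, dist_lake_w = dist_lake_w,
                 dist_road_w = dist_road_w,
                 start_day = as.integer(start_day),
                 end_day = as.integer(end_day)),
            class = "regime_spec")
}

# regime window lengths; checks that windows tile the 365-day circle
regime_day_lookup <- function(regimes) {
  lookup <- integer(365)
  for (r in seq_along(regimes)) {
    rg <- regimes[[r]]
    days <- if (rg$start_day <= rg$end_day) {
      rg$start_day:rg$end_day
    } else {
      c(rg$start_day:365, 1:rg$end_day)
    }
    if (any(lookup[days] != 0L)) {
      stop_ecoseasons("regime day-windows overlap", "invalid_config_error")
    }
    lookup[days] <- r
  }
  if (any(lookup == 0L)) {
    stop_ecoseasons("regime day-windows do not cover the ordinal year",
                    "invalid_config_error")
  }
  lookup
}

#' Canonical regime sets for simulation studies
#'
#' The package's reference study conditions. `"two_state"` is a two-season
#' population with a 3:1 step-scale ratio (summer 450 m vs winter 150 m gamma
#' scale) and distinct habitat preferences (summer: wetland and deciduous
#' forest; winter: coniferous forest and gentler slopes), switching at
#' ordinal days 100 and 300. `"one_state"` is the matching single-regime
#' (aseasonal) population using the averaged movement parameters.
#'
#' @param type `"two_state"` or `"one_state"`.
#' @param switch_days length-2 ordinal days of the two transitions
#'   (two-state only).
#' @return list of [regime_spec()]s.
#' @export
default_regimes <- function(type = c("two_state", "one_state"),
                            switch_days = c(100, 300)) {
  type <- match.arg(type)
  if (type == "one_state") {
    return(list(regime_spec("annual", step_scale = 300,
                            angular_concentration = 0.5,
                            habitat_weights = c(wetland = 0.75,
                                                coniferous_forest = 0.75),
                            start_day = 1, end_day = 365)))
  }
  list(
    regime_spec("summer", step_scale = 450, angular_concentration = 0.5,
                habitat_weights = c(wetland = 1.5, deciduous_forest = 0.5),
                slope_w = 0,
                start_day = switch_days[1], end_day = switch_days[2] - 1),
    regime_spec("winter", step_scale = 150, angular_concentration = 0.5,
                habitat_weights = c(coniferous_forest = 1.5),
                slope_w = -0.05,
                start_day = switch_days[2], end_day = switch_days[1] - 1))
}

#' Simulation configuration
#'
#' @param n_individuals number of independent individuals (>= 1).
#' @param regimes list of [regime_spec()]s whose day-windows tile the year.
#' @param fix_interval_hours nominal relocation interval in hours (> 0).
#' @param fix_jitter_minutes fix times are jittered uniformly on +/- this.
#' @param fix_failure_prob independent probability a scheduled fix is lost.
#' @param n_years number of simulated years.
#' @param start_date first day of the simulation (UTC midnight).
#' @param home_attraction site-fidelity strength: log-weight penalty per
#'   meter of candidate distance from the individual's home-range center
#'   (default 0.003, giving roughly kilometer-scale ranges at the default
#'   step scales; 0 disables range residency and lets walkers drift across
#'   the whole landscape).
#' @param rng_seed master seed; per-individual seeds are derived from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals, regimes, fix_interval_hours = 4,
                       fix_jitter_minutes = 15, fix_failure_prob = 0.05,
                       n_years = 2, start_date = "2021-01-01",
                       home_attraction = 0.003, rng_seed = 1) {
  if (n_individuals < 1 || fix_interval_hours <= 0 ||
      fix_failure_prob < 0 || fix_failure_prob >= 1) {
    stop_ecoseasons("invalid simulation configuration", "invalid_config_error")
  }
  regime_day_lookup(regimes)              # validates tiling
  structure(list(n_individuals = as.integer(n_individuals), regimes = regimes,
                 fix_interval_hours = fix_interval_hours,
                 fix_jitter_minutes = fix_jitter_minutes,
                 fix_failure_prob = fix_failure_prob,
                 n_years = as.integer(n_years),
                 start_date = as.Date(start_date),
                 home_attraction = home_attraction,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# von Mises sampler (Best & Fisher 1979 wrapped-Cauchy envelope), radians
rvonmises <- function(n, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(64L, ceiling((n - length(out)) * 1.7))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok]))))
  }
  out[seq_len(n)]
}

# per-cell log selection weight for one regime (vectorized over the grid)
regime_log_weight_field <- function(landscape, regime) {
  w <- regime$habitat_weights[landscape$classes][as.vector(landscape$land_cover)]
  w + regime$slope_w * as.vector(landscape$slope) +
    regime$northness_w * as.vector(landscape$northness) +
    regime$dist_lake_w * as.vector(landscape$dist_lake) +
    regime$dist_road_w * as.vector(landscape$dist_road)
}

#' Simulate one individual's track
#'
#' Biased correlated random walk with discrete-choice habitat selection: at
#' each scheduled fix, `n_candidates` candidate endpoints are drawn from the
#' current regime's gamma step-length and von Mises turning-angle laws, and
#' one is chosen with probability proportional to exp(selection weight at the
#' endpoint). Candidates off the landscape get weight zero; if every candidate
#' is off-landscape the whole candidate set is redrawn (bounded retries).
#' Fix times carry uniform jitter and independent dropout; the walk itself
#' advances through lost fixes, so dropout creates irregular gaps for the
#' resampler to handle. The true regime label is recorded per fix.
#'
#' Each individual is range-resident: a home-range center is drawn once (in
#' the central portion of the landscape) and every candidate endpoint's
#' log-weight is penalized by `home_attraction` per meter of distance from
#' it, the discrete-choice analog of an Ornstein-Uhlenbeck centering
#' tendency. Set `home_attraction = 0` in the configuration for free-ranging
#' walkers.
#'
#' @param landscape a `landscape_stack`.
#' @param regimes list of [regime_spec()]s tiling the year.
#' @param config a [sim_config()] (its `regimes` field is ignored in favor of
#'   the `regimes` argument so single-track use stays self-contained).
#' @param individual_id identifier stored on the output rows.
#' @param seed RNG seed for this track.
#' @param n_candidates candidate endpoints per step (discrete-choice
#'   approximation of the habitat-weighted redistribution kernel).
#' @return data.frame: `individual_id`, `timestamp` (POSIXct UTC), `x`, `y`,
#'   `true_regime`.
#' @export
simulate_track <- function(landscape, regimes, config, individual_id,
                           seed, n_candidates = 30) {
  g <- landscape$grid
  lookup <- regime_day_lookup(regimes)
  set.seed(seed)

  n_fix <- floor(config$n_years * 365 * 24 / config$fix_interval_hours) + 1L
  sched_h <- (seq_len(n_fix) - 1L) * config$fix_interval_hours
  jit <- stats::runif(n_fix, -config$fix_jitter_minutes,
                      config$fix_jitter_minutes) / 60
  jit[1] <- 0
  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  times <- t0 + (sched_h + jit) * 3600
  lost <- stats::runif(n_fix) < config$fix_failure_prob
  lost[1] <- FALSE
  regime_ix <- lookup[ordinal_day(times)]

  wfields <- lapply(regimes, regime_log_weight_field, landscape = landscape)
  # pre-drawn step lengths and turns, per step x candidate, regime-specific
  steps <- matrix(0, n_fix, n_candidates)
  turns <- matrix(0, n_fix, n_candidates)
  for (r in seq_along(regimes)) {
    rows <- which(regime_ix == r)
    if (!length(rows)) next
    m <- length(rows) * n_candidates
    steps[rows, ] <- stats::rgamma(m, shape = regimes[[r]]$step_shape,
                                   scale = regimes[[r]]$step_scale)
    turns[rows, ] <- rvonmises(m, regimes[[r]]$angular_concentration)
  }

  x <- numeric(n_fix); y <- numeric(n_fix)
  cx0 <- stats::runif(1, g$xmin + 0.2 * (g$xmax - g$xmin),
                      g$xmax - 0.2 * (g$xmax - g$xmin))
  cy0 <- stats::runif(1, g$ymin + 0.2 * (g$ymax - g$ymin),
                      g$ymax - 0.2 * (g$ymax - g$ymin))
  x[1] <- cx0; y[1] <- cy0
  attraction <- config$home_attraction %||% 0
  heading <- stats::runif(1, -pi, pi)

  for (i in seq_len(n_fix)[-1]) {
    r <- regime_ix[i]
    st <- steps[i, ]; tu <- turns[i, ]
    for (attempt in seq_len(20L)) {
      ang <- heading + tu
      cx <- x[i - 1L] + st * cos(ang)
      cy <- y[i - 1L] + st * sin(ang)
      idx <- cell_index(g, cx, cy)
      ok <- !is.na(idx[, 1])
      if (any(ok)) break
      st <- stats::rgamma(n_candidates, shape = regimes[[r]]$step_shape,
                          scale = regimes[[r]]$step_scale)
      tu <- rvonmises(n_candidates, regimes[[r]]$angular_concentration)
    }
    if (!any(ok)) {
      stop_ecoseasons(sprintf(
        "walker stuck at (%.1f, %.1f) on step %d: all candidates off-landscape",
        x[i - 1L], y[i - 1L], i), "stuck_walker_error")
    }
    lin <- idx[ok, 1] + (idx[ok, 2] - 1L) * g$n_rows
    lw <- wfields[[r]][lin] -
      attraction * sqrt((cx[ok] - cx0)^2 + (cy[ok] - cy0)^2)
    w <- exp(lw - max(lw))
    pick <- which(ok)[sample.int(sum(ok), 1L, prob = w)]
    x[i] <- cx[pick]; y[i] <- cy[pick]
    heading <- atan2(y[i] - y[i - 1L], x[i] - x[i - 1L])
  }

  keep <- !lost
  data.frame(individual_id = as.character(individual_id),
             timestamp = times[keep], x = x[keep], y = y[keep],
             true_regime = vapply(regimes, `[[`, "", "name")[regime_ix[keep]],
             stringsAsFactors = FALSE)
}

#' Simulate a population of independent individuals
#'
#' Individuals share the regime day-windows (seasons are population-level
#' states); each gets a seed derived deterministically from `rng_seed`, so the
#' whole population is reproducible.
#'
#' @param landscape a `landscape_stack`.
#' @param config a [sim_config()].
#' @return list with `tracks` (one stacked data.frame) and `calendar` (the
#'   true [season_calendar()] implied by the regime windows).
#' @export
simulate_population <- function(landscape, config) {
  tracks <- vector("list", config$n_individuals)
  for (i in seq_len(config$n_individuals)) {
    tracks[[i]] <- tryCatch(
      simulate_track(landscape, config$regimes, config,
                     individual_id = sprintf("ind%02d", i),
                     seed = derive_seed(config$rng_seed, i)),
      ecoseasons_error = function(e) {
        stop_ecoseasons(sprintf("individual ind%02d: %s", i,
                                conditionMessage(e)),
                        class(e)[1])
      })
  }
  states <- data.frame(
    label = vapply(config$regimes, `[[`, "", "name"),
    start_day = vapply(config$regimes, `[[`, 1L, "start_day"),
    end_day = vapply(config$regimes, `[[`, 1L, "end_day"),
    stringsAsFactors = FALSE)
  list(tracks = do.call(rbind, tracks),
       calendar = season_calendar(states,
                                  provenance = list(source = "simulation",
                                                    seed = config$rng_seed)))
}

#' Simulate daily weather
#'
#' Sinusoidal annual mean temperature (configured winter minimum and summer
#' maximum) plus Gaussian noise; snow depth is proportional to the negative
#' part of the smoothed (noiseless) temperature curve, so it is positive only
#' when the smoothed temperature is below freezing and, by construction,
#' negatively associated with growing-degree-day accumulation.
#'
#' @param n_years number of years (>= 1).
#' @param seed RNG seed.
#' @param start_year first calendar year.
#' @param min_temp,max_temp annual extremes of the smoothed curve, degrees C.
#' @param noise_sd daily temperature noise SD, degrees C.
#' @param snow_per_degree cm of snow depth per degree below zero of the
#'   smoothed curve.
#' @param snow_noise_sd SD of the (clamped) snow-depth noise, cm.
#' @return data.frame: `date`, `mean_temp`, `snow_depth`.
#' @export
simulate_weather <- function(n_years, seed, start_year = 2019,
                             min_temp = -17.8, max_temp = 23.3,
                             noise_sd = 2.5, snow_per_degree = 3,
                             snow_noise_sd = 3) {
  stopifnot(n_years >= 1)
  set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1)),
               by = "day")
  od <- ordinal_day(dates)
  mid <- (max_temp + min_temp) / 2
  amp <- (max_temp - min_temp) / 2
  curve <- mid + amp * cos(2 * pi * (od - 196) / 365)   # peak mid-July
  temp <- curve + stats::rnorm(length(dates), 0, noise_sd)
  snow <- ifelse(curve < 0,
                 pmax(0, -curve * snow_per_degree +
                        stats::rnorm(length(dates), 0, snow_noise_sd)),
                 0)
  data.frame(date = dates, mean_temp = temp, snow_depth = snow)
}

#' Write tracks as Movebank-style CSV
#'
#' Columns `individual_id`, `timestamp` (ISO-8601 UTC), `x`, `y`, plus
#' `true_regime` when present (simulated ground truth).
#'
#' @param tracks track data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  out <- tracks
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read tracks from Movebank-style CSV
#'
#' @param path CSV path with at least `individual_id`, `timestamp`, `x`, `y`.
#' @return track data.frame with POSIXct UTC timestamps.
#' @export
read_tracks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("individual_id", "timestamp", "x", "y") %in% names(d)))
  d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                           "%Y-%m-%d %H:%M:%S"))
  d$individual_id <- as.character(d$individual_id)
  d
}
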