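## Simplified per-individual, per-season resource selection: time-weighted
## kernel utilization distributions on the landscape grid, used/available
## logistic approximation of the Poisson point process, and AICc-weighted
## population pooling. This is a documented simplification of the weighted
## autocorrelated KDE / weighted RSF framework: the segmenting rules,
## covariate scheme, UD levels, pooling and significance rule are retained,
## while autocorrelation-adjusted weights are replaced by plain time-span
## weights (each fix weighted by half the gap to each temporal neighbor).

#' Resample a track for resource selection
#'
#' [resample_track()] with the selection-stage defaults: 4-hour target
#' interval, 1-hour tolerance (used to standardize high-frequency collars
#' before selection analysis).
#'
#' @param track track data.frame.
#' @param target_hours nominal interval (default 4).
#' @param tol_hours tolerance (default 1).
#' @return the resampled track.
#' @export
resample_for_rsf <- function(track, target_hours = 4, tol_hours = 1) {
  resample_track(track, target_hours = target_hours, tol_hours = tol_hours)
}

#' Split tracks into individual-season segments
#'
#' Fixes are grouped by individual, calendar state, and season-year (a state
#' spanning the year boundary belongs to the year in which it begins). Fixes
#' closer than `buffer_days` to any transition date (circular day distance)
#' are excluded, and segments with fewer than `min_locs` remaining fixes are
#' dropped with a log entry.
#'
#' @param tracks track data.frame for one population.
#' @param calendar a `season_calendar`.
#' @param min_locs minimum locations per segment (default 50).
#' @param buffer_days transition buffer (default 14; fixes at exactly
#'   `buffer_days` are retained).
#' @return list of `season_segment`s (`individual_id`, `state`, `year`,
#'   `fixes`, `n_locations`); dropped segments are reported via `message()`.
#' @export
segment_locations <- function(tracks, calendar, min_locs = 50,
                              buffer_days = 14) {
  stopifnot(inherits(calendar, "season_calendar"))
  od <- ordinal_day(tracks$timestamp)
  tdays <- calendar$transitions$day
  near_transition <- if (length(tdays)) {
    apply(abs(outer(od, tdays, circ_diff)), 1, min) < buffer_days
  } else {
    rep(FALSE, length(od))
  }
  tr <- tracks[!near_transition, , drop = FALSE]
  od <- od[!near_transition]
  state <- state_of_day(calendar, od)
  yr <- as.integer(format(tr$timestamp, "%Y"))
  # a wrapping state started the previous calendar year for days <= end_day
  for (s in seq_len(nrow(calendar$states))) {
    st <- calendar$states[s, ]
    if (st$start_day > st$end_day) {
      w <- state == st$label & od <= st$end_day
      yr[w] <- yr[w] - 1L
    }
  }
  key <- interaction(tr$individual_id, state, yr, drop = TRUE)
  segs <- list()
  for (k in levels(key)) {
    rows <- which(key == k)
    fixes <- tr[rows, , drop = FALSE]
    fixes <- fixes[order(fixes$timestamp), , drop = FALSE]
    seg <- structure(list(individual_id = fixes$individual_id[1],
                          state = state[rows][1], year = yr[rows][1],
                          fixes = fixes, n_locations = nrow(fixes)),
                     class = "season_segment")
    if (seg$n_locations < min_locs) {
      message(sprintf("dropping %s / %s / %d: %d location(s) < %d",
                      seg$individual_id, seg$state, seg$year,
                      seg$n_locations, min_locs))
    } else {
      segs[[length(segs) + 1L]] <- seg
    }
  }
  segs
}

# time-span weight per fix: half the gap to each temporal neighbor; boundary
# fixes take the full gap to their single neighbor, so regular sampling
# yields equal weights. Normalized to mean 1.
time_span_weights <- function(times) {
  n <- length(times)
  if (n == 1) return(1)
  gaps <- diff(as.numeric(times))
  w <- c(gaps[1], (gaps[-length(gaps)] + gaps[-1]) / 2, gaps[length(gaps)])
  w / mean(w)
}

#' Fit a utilization distribution on the landscape grid
#'
#' Gaussian kernel density over the grid cells with a plug-in (normal
#' reference) bandwidth per coordinate, each fix weighted by the time span it
#' represents. The discrete cell masses are normalized to 1; the 50% and 95%
#' isopleths are the smallest superlevel cell sets holding at least that
#' fraction of mass, so the 50% region nests inside the 95% region by
#' construction.
#'
#' @param segment a `season_segment`.
#' @param landscape a `landscape_stack` providing the grid.
#' @param min_bandwidth floor on the bandwidth in meters (guards single-cell
#'   degeneracy).
#' @return a `utilization_distribution`: `density` (matrix of cell masses
#'   summing to 1), `iso50`, `iso95` (logical cell masks), `bandwidth`,
#'   `mass50`, `mass95`.
#' @export
fit_ud <- function(segment, landscape, min_bandwidth = 0) {
  stopifnot(inherits(segment, "season_segment"))
  g <- landscape$grid
  fx <- segment$fixes
  if (stats::sd(fx$x) < 1e-9 && stats::sd(fx$y) < 1e-9) {
    stop_ecoseasons(
      "all fixes identical; supply min_bandwidth > 0 to fit a degenerate UD",
      "degenerate_ud_error")
  }
  w <- time_span_weights(fx$timestamp)
  w <- w / sum(w)
  n <- nrow(fx)
  # normal-reference plug-in bandwidth per coordinate, shared floor
  bw <- pmax(min_bandwidth,
             1.06 * c(stats::sd(fx$x), stats::sd(fx$y)) * n^(-1 / 5))
  bw[bw == 0] <- max(bw, g$cell_size)
  cx <- g$xmin + (seq_len(g$n_cols) - 0.5) * g$cell_size
  cy <- g$ymax - (seq_len(g$n_rows) - 0.5) * g$cell_size
  dx <- stats::dnorm(outer(cx, fx$x, "-") / bw[1])      # n_cols x n
  dy <- stats::dnorm(outer(cy, fx$y, "-") / bw[2])      # n_rows x n
  dens <- dy %*% (w * t(dx))                            # n_rows x n_cols
  dens <- dens / sum(dens)
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[ord])
  iso_mask <- function(level) {
    cut <- which(cum >= level)[1]
    mask <- matrix(FALSE, g$n_rows, g$n_cols)
    mask[ord[seq_len(cut)]] <- TRUE
    mask
  }
  iso50 <- iso_mask(0.50); iso95 <- iso_mask(0.95)
  structure(list(density = dens, iso50 = iso50, iso95 = iso95,
                 bandwidth = bw, mass50 = sum(dens[iso50]),
                 mass95 = sum(dens[iso95])),
            class = "utilization_distribution")
}

#' @export
print.utilization_distribution <- function(x, ...) {
  cat(sprintf("UD: bandwidth (%.0f, %.0f) m; 50%% isopleth %d cells (mass %.3f), 95%% %d cells (mass %.3f)\n",
              x$bandwidth[1], x$bandwidth[2], sum(x$iso50), x$mass50,
              sum(x$iso95), x$mass95))
  invisible(x)
}

# ridge-penalized logistic IRLS fallback for separated fits
ridge_logistic <- function(X, y, w, lambda = 1e-3) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0
  for (it in 1:50) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wirls <- w * mu * (1 - mu) + 1e-10
    z <- eta + (y - mu) / (mu * (1 - mu) + 1e-10)
    new <- solve(crossprod(X, wirls * X) + pen, crossprod(X, wirls * z))
    if (max(abs(new - beta)) < 1e-8) { beta <- drop(new); break }
    beta <- drop(new)
  }
  V <- solve(crossprod(X, wirls * X) + pen)
  list(coef = beta, vcov = V)
}

#' Fit a resource selection function for one segment
#'
#' Used points are the segment fixes inside the chosen UD isopleth; available
#' points are sampled uniformly within that isopleth at `availability_ratio`
#' per used point. Coefficients come from weighted logistic regression with
#' heavy down-weighting of available points (the infinitely-weighted-logistic
#' approximation to the continuous Poisson point process); used points also
#' carry their time-span weights. Predictors: land cover (open water as the
#' reference class), northness, slope, distance to lake, distance to road —
#' no interactions — plus a squared-distance-from-centroid nuisance term
#' (`range_dist2`, per km^2) standing in for the integrated ranging kernel:
#' it absorbs the concentration of use toward the home-range center so
#' smooth covariate gradients across the range do not masquerade as
#' selection. The nuisance coefficient is reported but never pooled.
#' A land-cover class absent from both used and available
#' points is marked inestimable; detected separation triggers a logged
#' ridge-penalized refit.
#'
#' @param segment a `season_segment`.
#' @param ud its `utilization_distribution`.
#' @param landscape a `landscape_stack`.
#' @param level isopleth level, 50 or 95.
#' @param availability_ratio available points per used point (default 10).
#' @param seed RNG seed for availability sampling.
#' @return an `rsf_fit`: `coefficients`, `vcov`, `aicc`, `n_used`,
#'   `n_available`, `ud_level`, `inestimable`, `ridge` (penalty used or NA).
#' @export
fit_rsf <- function(segment, ud, landscape, level = 95,
                    availability_ratio = 10, seed = 1) {
  stopifnot(level %in% c(50, 95))
  g <- landscape$grid
  mask <- if (level == 50) ud$iso50 else ud$iso95
  fx <- segment$fixes
  idx <- cell_index(g, fx$x, fx$y)
  lin <- idx[, 1] + (idx[, 2] - 1L) * g$n_rows
  inside <- !is.na(lin) & mask[lin]
  used <- fx[inside, , drop = FALSE]
  w_used <- time_span_weights(fx$timestamp)[inside]
  n_used <- nrow(used)
  if (n_used < 10) {
    stop_ecoseasons(sprintf("only %d used point(s) inside the %d%% isopleth",
                            n_used, level), "degenerate_ud_error")
  }
  set.seed(seed)
  cells <- which(mask)
  pick <- cells[sample.int(length(cells), availability_ratio * n_used,
                           replace = TRUE)]
  pi_ <- ((pick - 1L) %% g$n_rows) + 1L
  pj <- ((pick - 1L) %/% g$n_rows) + 1L
  ax <- g$xmin + (pj - 1L + stats::runif(length(pick))) * g$cell_size
  ay <- g$ymax - (pi_ - 1L + stats::runif(length(pick))) * g$cell_size
  av <- data.frame(x = ax, y = ay)

  cov_u <- landscape_values_at(landscape, used$x, used$y)
  cov_a <- landscape_values_at(landscape, av$x, av$y)
  dat <- rbind(cov_u, cov_a)
  dat$used <- rep(c(1, 0), c(n_used, nrow(av)))
  dat$w <- c(w_used, rep(1000, nrow(av)))
  # ranging-kernel nuisance: a bivariate quadratic in the centered
  # coordinates (an elliptical-Gaussian ranging model on the log scale)
  # absorbs the concentration of use toward the home-range center — the role
  # of the integrated ranging model in an iRSF — so smooth covariate
  # gradients across the range do not masquerade as selection. Coordinates
  # in km; the range_* coefficients are reported but never pooled.
  ctr <- c(stats::weighted.mean(used$x, w_used),
           stats::weighted.mean(used$y, w_used))
  rx <- (c(used$x, av$x) - ctr[1]) / 1000
  ry <- (c(used$y, av$y) - ctr[2]) / 1000
  dat$range_x <- rx; dat$range_y <- ry
  dat$range_xx <- rx^2; dat$range_yy <- ry^2; dat$range_xy <- rx * ry
  dat$land_cover <- factor(dat$land_cover, levels = LAND_COVER_CLASSES)
  present <- levels(droplevels(dat$land_cover))
  inestimable <- setdiff(setdiff(LAND_COVER_CLASSES, "open_water"), present)
  dat$land_cover <- droplevels(dat$land_cover)
  dat$land_cover <- stats::relevel(dat$land_cover,
                                   ref = if ("open_water" %in% present)
                                     "open_water" else present[1])

  form <- used ~ land_cover + northness + slope + dist_lake + dist_road +
    range_x + range_y + range_xx + range_yy + range_xy
  fit <- suppressWarnings(stats::glm(form, data = dat,
                                     family = stats::binomial(),
                                     weights = w))
  beta <- stats::coef(fit)
  ridge <- NA_real_
  hab <- !grepl("^range_", names(beta))
  if (!fit$converged || any(is.na(beta[hab])) ||
      any(abs(beta[hab][-1]) > 15, na.rm = TRUE)) {
    X <- stats::model.matrix(form, dat)
    rfit <- ridge_logistic(X, dat$used, dat$w, lambda = 1e-3)
    beta <- stats::setNames(rfit$coef, colnames(X))
    V <- rfit$vcov
    ridge <- 1e-3
    message(sprintf("separation detected in %s/%s/%d: ridge penalty %.0e applied",
                    segment$individual_id, segment$state, segment$year, ridge))
  } else {
    # day-cluster robust covariance: fixes within a day are serially
    # dependent, so the naive binomial covariance understates uncertainty;
    # availability points are independent draws (one singleton cluster each)
    day_cl <- c(paste0("u", as.Date(used$timestamp, tz = "UTC")),
                paste0("a", seq_len(nrow(av))))
    V <- tryCatch(sandwich::vcovCL(fit, cluster = day_cl),
                  error = function(e) stats::vcov(fit))
  }
  p <- length(beta)
  ll <- as.numeric(stats::logLik(fit))
  aicc <- -2 * ll + 2 * p + 2 * p * (p + 1) / max(1, n_used - p - 1)
  structure(list(coefficients = beta, vcov = V, aicc = aicc,
                 n_used = n_used, n_available = nrow(av), ud_level = level,
                 inestimable = inestimable, ridge = ridge,
                 individual_id = segment$individual_id,
                 state = segment$state, year = segment$year),
            class = "rsf_fit")
}

#' @export
coef.rsf_fit <- function(object, ...) object$coefficients

#' @export
vcov.rsf_fit <- function(object, ...) object$vcov

#' @export
confint.rsf_fit <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(object$coefficients - z * se, object$coefficients + z * se)
  colnames(out) <- paste(100 * c((1 - level) / 2, 1 - (1 - level) / 2), "%")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("RSF fit: %s / %s / %d at %d%% UD (%d used, %d available, AICc %.1f)\n",
              x$individual_id, x$state, x$year, x$ud_level, x$n_used,
              x$n_available, x$aicc))
  print(round(x$coefficients, 4))
  if (length(x$inestimable)) {
    cat("Inestimable classes:", paste(x$inestimable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pool segment-level RSF fits to the population level
#'
#' Per predictor, the pooled estimate is the weighted arithmetic mean of the
#' per-segment coefficients, with weights from relative AICc (default) or
#' equal. The 95% confidence interval uses the t distribution on the
#' across-segment weighted variance; a continuous predictor is flagged
#' significant when its interval excludes zero. Predictors estimable in fewer
#' than 2 segments are reported without an interval.
#'
#' @param fits list of `rsf_fit`s (same UD level).
#' @param weighting `"aicc"` (relative AICc weights within the fit set) or
#'   `"equal"`.
#' @return a `population_rsf` data.frame-backed object: per predictor the
#'   pooled `estimate`, `lwr`, `upr`, `significant`, `n_segments`; plus the
#'   `weights` used.
#' @export
pool_population <- function(fits, weighting = c("aicc", "equal")) {
  weighting <- match.arg(weighting)
  stopifnot(length(fits) >= 1)
  aicc <- vapply(fits, `[[`, 0, "aicc")
  wts <- if (weighting == "aicc") {
    d <- aicc - min(aicc)
    exp(-0.5 * d) / sum(exp(-0.5 * d))
  } else {
    rep(1 / length(fits), length(fits))
  }
  preds <- unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  preds <- setdiff(preds, c("(Intercept)", grep("^range_", preds, value = TRUE)))
  rows <- lapply(preds, function(p) {
    have <- vapply(fits, function(f)
      p %in% names(f$coefficients) && !is.na(f$coefficients[p]), TRUE)
    b <- vapply(fits[have], function(f) unname(f$coefficients[p]), 0)
    w <- wts[have] / sum(wts[have])
    est <- sum(w * b)
    if (sum(have) < 2) {
      return(data.frame(predictor = p, estimate = est, lwr = NA, upr = NA,
                        significant = NA, n_segments = sum(have)))
    }
    # weighted across-segment variance of the mean; when the weights collapse
    # onto one segment (effective n ~ 1) the interval is undefined, as with a
    # single estimable segment
    denom <- 1 - sum(w^2)
    if (denom < 1e-8) {
      return(data.frame(predictor = p, estimate = est, lwr = NA, upr = NA,
                        significant = NA, n_segments = sum(have)))
    }
    v <- sum(w * (b - est)^2) / denom
    se <- sqrt(v * sum(w^2))
    tq <- stats::qt(0.975, df = sum(have) - 1)
    data.frame(predictor = p, estimate = est, lwr = est - tq * se,
               upr = est + tq * se,
               significant = (est - tq * se) > 0 | (est + tq * se) < 0,
               n_segments = sum(have))
  })
  structure(list(table = do.call(rbind, rows), weights = wts,
                 weighting = weighting, n_fits = length(fits)),
            class = "population_rsf")
}

#' @export
coef.population_rsf <- function(object, ...) {
  stats::setNames(object$table$estimate, object$table$predictor)
}

#' @export
confint.population_rsf <- function(object, ...) {
  out <- as.matrix(object$table[, c("lwr", "upr")])
  rownames(out) <- object$table$predictor
  colnames(out) <- c("2.5 %", "97.5 %")
  out
}

#' @export
print.population_rsf <- function(x, ...) {
  cat(sprintf("Population RSF (%s weights, %d segment fits)\n",
              x$weighting, x$n_fits))
  tab <- x$table
  tab$estimate <- round(tab$estimate, 3)
  tab$lwr <- round(tab$lwr, 3); tab$upr <- round(tab$upr, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.population_rsf <- function(object, ...) {
  print(object)
  sig <- object$table$predictor[!is.na(object$table$significant) &
                                  object$table$significant]
  cat(if (length(sig)) paste("Significant (95% CI excludes 0):",
                             paste(sig, collapse = ", "), "\n")
      else "No predictor significant at the 95% level\n")
  invisible(object)
}
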