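## The central estimator: run the full seasonality pipeline on a daily
## space-use matrix and return a classed fit. Stage order: HINoV screen ->
## ANOVA screen -> k selection -> bootstrap-stability k-means -> moving-window
## smoothing -> transition dating -> PCA characterization. When no candidate
## k is stable, the fit reports "no seasonal states" instead of forcing a
## calendar (the outcome expected of populations without seasonal structure).

# label for each of the 365 days given labels on a subset of days: unlabeled
# days take the label of the circularly nearest labeled day (ties -> earlier)
fill_labels <- function(days_used, labels, n = 365) {
  out <- rep(NA, n)
  out[days_used] <- labels
  miss <- which(is.na(out))
  for (d in miss) {
    dist <- abs(circ_diff(days_used, d, n))
    out[d] <- labels[which.min(dist)]
  }
  out
}

#' Delineate seasonal space-use states
#'
#' Runs the full season-delineation pipeline on a prepared daily space-use
#' matrix: HINoV noisy-variable screening, ANOVA screening against a
#' preliminary k-means partition, elbow + silhouette selection of k,
#' bootstrap-Jaccard stability assessment (instability of any cluster under
#' any seed voids a candidate k; when elbow and silhouette disagree both are
#' tried and the smaller stable k wins), 5-day moving-window smoothing of the
#' first seed's day assignments, 8-day-run transition dating, and PCA
#' characterization of the resulting states.
#'
#' @param dm a transformed, collinearity-filtered `daily_matrix` (see
#'   [prepare_daily_matrix()]).
#' @param k_min,k_max candidate cluster range (defaults 2 and 8).
#' @param B bootstrap replicates per seed (default 5000; 200 is a practical
#'   fast profile).
#' @param n_seeds outer random-number seeds for stability (default 10).
#' @param gamma per-cluster mean-Jaccard stability threshold (default 0.75).
#' @param window smoothing window in days (odd, default 5).
#' @param run_length consecutive-day run required to date a transition
#'   (default 8).
#' @param alpha ANOVA screen level (default 0.05).
#' @param anova_mode see [anova_screen()].
#' @param k_probe probe k for the screening stages (default `k_min`).
#' @param min_state_days temporal-coherence floor: every final state must
#'   last at least this many days, or the delineation is rejected as
#'   non-seasonal. The default, `2 * run_length + window`, is the method's
#'   own resolution: a state must be able to contain the two
#'   `run_length`-day runs that date its boundaries plus the smoothing
#'   margin. An aseasonal population whose (spuriously stable) cluster
#'   labels oscillate through many short blocks fails this floor.
#' @param seed master RNG seed; every stochastic stage derives from it.
#' @return a `season_states` fit: `calendar` (a [season_calendar()] or NULL),
#'   `no_states` (TRUE when no candidate k was stable), `hinov`, `anova`,
#'   `selection`, `stability` (report for the accepted k, or the last
#'   attempted), `attempts` (all stability reports), `pca`, `labels_raw`,
#'   `labels_smoothed` (length-365), `matrix` (screened `daily_matrix`),
#'   and `settings`.
#' @examples
#' \donttest{
#' ls <- make_landscape(MAINLAND_PROPORTIONS, grid_spec(60, 60), seed = 1)
#' regs <- list(
#'   regime_spec("summer", 450, habitat_weights = c(wetland = 1.5),
#'               start_day = 100, end_day = 299),
#'   regime_spec("winter", 150, habitat_weights = c(coniferous_forest = 1.5),
#'               start_day = 300, end_day = 99))
#' pop <- simulate_population(ls, sim_config(4, regs, n_years = 1, rng_seed = 2))
#' dm <- prepare_daily_matrix(pop$tracks, ls)
#' fit <- season_states(dm, B = 50, n_seeds = 2, seed = 3)
#' print(fit)
#' }
#' @export
season_states <- function(dm, k_min = 2, k_max = 8, B = 5000, n_seeds = 10,
                          gamma = 0.75, window = 5, run_length = 8,
                          alpha = 0.05,
                          anova_mode = c("remove_nonsignificant",
                                         "remove_significant"),
                          k_probe = k_min,
                          min_state_days = 2 * run_length + window,
                          seed = 1) {
  stopifnot(inherits(dm, "daily_matrix"))
  anova_mode <- match.arg(anova_mode)
  settings <- list(k_min = k_min, k_max = k_max, B = B, n_seeds = n_seeds,
                   gamma = gamma, window = window, run_length = run_length,
                   alpha = alpha, anova_mode = anova_mode, k_probe = k_probe,
                   min_state_days = min_state_days, seed = seed)

  ## --- variable screening -------------------------------------------------
  hinov <- hinov_screen(dm, k_probe = k_probe, seed = derive_seed(seed, 11))
  for (v in c(hinov$flagged, hinov$excluded)) {
    j <- match(v, dm$meta$column)
    dm$meta$retained[j] <- FALSE
    dm$meta$reason[j] <- "hinov"
  }
  if (anova_mode == "remove_significant") {
    message("anova_mode = 'remove_significant' applies the literal removal ",
            "rule, which discards the variables that separate the candidate ",
            "clusters; see the methods vignette")
  }

  no_states_result <- function(anova = NULL, selection = NULL,
                               stability = NULL, attempts = list(),
                               labels_raw = NULL, labels_smoothed = NULL,
                               rejected_calendar = NULL) {
    structure(list(calendar = NULL, no_states = TRUE, hinov = hinov,
                   anova = anova, selection = selection,
                   stability = stability, attempts = attempts, pca = NULL,
                   labels_raw = labels_raw, labels_smoothed = labels_smoothed,
                   rejected_calendar = rejected_calendar, matrix = dm,
                   settings = settings),
              class = "season_states")
  }

  ## --- screen / cluster / date loop ---------------------------------------
  # The ANOVA screen needs a temporally coherent candidate partition, and the
  # clustering benefits from the screened variable set; the two are iterated
  # to a fixed point (screening against the delineated states and
  # re-clustering when variables fall out), capped at three rounds.
  prev_fit <- NULL
  for (round in 1:3) {
    prelim_days <- which(!dm$missing & stats::complete.cases(
      retained_matrix(dm, complete = FALSE)))
    if (is.null(prev_fit)) {
      # Round 1 candidate: preliminary k-means labels turned into candidate
      # CALENDAR STATES by the pipeline's own machinery (mode filtering
      # iterated to its fixed point, then run-length transition dating).
      # Seasons are temporally coherent by definition, so variables are
      # screened on whether they distinguish contiguous candidate states; an
      # arbitrary scattered split of the day cloud is not evidence of
      # seasonality and mixes out of the candidate blocks. Holm adjustment
      # keeps an aseasonal population from retaining lucky variables at the
      # family level.
      m <- retained_matrix(dm)
      m <- m[stats::complete.cases(m), , drop = FALSE]
      prelim <- seeded_kmeans(m, k_probe, derive_seed(seed, 12))
      cand_smooth <- fill_labels(prelim_days, prelim$cluster)
      for (it in 1:20) {
        nxt <- smooth_assignments(cand_smooth, window = window)
        if (identical(nxt, cand_smooth)) break
        cand_smooth <- nxt
      }
      cand_cal <- tryCatch(
        suppressMessages(transition_dates(cand_smooth,
                                          run_length = run_length)),
        ecoseasons_error = function(e) NULL)
      # when the preliminary partition is too ragged to date, fall back to
      # the smoothed labels; the stability gate and the state-duration floor
      # downstream remain the arbiters of seasonality
      candidate <- if (is.null(cand_cal)) cand_smooth[prelim_days]
                   else state_of_day(cand_cal, prelim_days)
    } else {
      candidate <- state_of_day(prev_fit$calendar, prelim_days)
    }
    if (length(unique(candidate)) < 2 || any(table(candidate) < 2)) {
      return(no_states_result())
    }
    anova <- anova_screen(dm, candidate, alpha = alpha, mode = anova_mode,
                          adjust = "holm")
    removals <- intersect(anova$remove,
                          dm$meta$column[dm$meta$retained])
    for (v in removals) {
      j <- match(v, dm$meta$column)
      dm$meta$retained[j] <- FALSE
      dm$meta$reason[j] <- sprintf("anova (%s, round %d)", anova_mode, round)
    }
    if (sum(dm$meta$retained) < 1) {
      return(no_states_result(anova = anova))
    }
    if (!is.null(prev_fit) && !length(removals)) {
      return(prev_fit)                    # screen/cluster fixed point reached
    }

    selection <- select_k(dm, k_min = k_min, k_max = k_max,
                          seed = derive_seed(seed, 13))
    candidates <- sort(unique(c(selection$k_elbow, selection$k_silhouette)))
    attempts <- list()
    stab <- NULL
    for (k in candidates) {               # smaller stable k preferred
      rep_k <- stable_kmeans(dm, k, B = B, n_seeds = n_seeds, gamma = gamma,
                             seed = derive_seed(seed, 14))
      attempts[[as.character(k)]] <- rep_k
      if (rep_k$stable) {
        stab <- rep_k
        break
      }
    }
    if (is.null(stab)) {
      return(no_states_result(anova = anova, selection = selection,
                              stability = attempts[[length(attempts)]],
                              attempts = attempts))
    }

    mm <- retained_matrix(dm, complete = FALSE)
    days_used <- which(!dm$missing & stats::complete.cases(mm))
    labels_raw <- fill_labels(days_used, sprintf("S%02d", stab$assignment))
    labels_smoothed <- smooth_assignments(labels_raw, window = window)
    calendar <- tryCatch(
      transition_dates(
        labels_smoothed, run_length = run_length,
        provenance = list(k = stab$k, B = B, n_seeds = n_seeds,
                          gamma = gamma, window = window, seed = seed)),
      ecoseasons_error = function(e) NULL)
    durations <- if (is.null(calendar)) 0 else {
      ((calendar$states$end_day - calendar$states$start_day) %% 365) + 1
    }
    if (is.null(calendar) || any(durations < min_state_days)) {
      if (!is.null(calendar)) {
        message(sprintf(
          "delineation rejected: shortest state lasts %d day(s) < %d; %s",
          min(durations), min_state_days,
          "assignments are not temporally coherent at the method's resolution"))
      }
      return(no_states_result(anova = anova, selection = selection,
                              stability = stab, attempts = attempts,
                              labels_raw = labels_raw,
                              labels_smoothed = labels_smoothed,
                              rejected_calendar = calendar))
    }
    prev_fit <- structure(
      list(calendar = calendar, no_states = FALSE, hinov = hinov,
           anova = anova, selection = selection, stability = stab,
           attempts = attempts, pca = characterize_pca(dm, calendar),
           labels_raw = labels_raw, labels_smoothed = labels_smoothed,
           matrix = dm, settings = settings),
      class = "season_states")
  }
  prev_fit
}

#' @export
print.season_states <- function(x, ...) {
  if (x$no_states) {
    cat("Seasonal space-use states: no seasonal states\n")
    cat("(no candidate k passed the bootstrap-Jaccard stability rule)\n")
  } else {
    cat(sprintf("Seasonal space-use states: k = %d stable state(s)\n",
                x$stability$k))
    print(x$calendar)
    if (!is.null(x$pca)) {
      cat(sprintf("Components 1-2 describe %.1f%% of daily space-use variation\n",
                  sum(x$pca$pct_variance[1:2])))
    }
  }
  invisible(x)
}

#' @export
summary.season_states <- function(object, ...) {
  x <- object
  cat("== Season delineation fit ==\n")
  cat(sprintf("Variables retained: %d of %d\n", sum(x$matrix$meta$retained),
              nrow(x$matrix$meta)))
  dropped <- x$matrix$meta[!x$matrix$meta$retained, , drop = FALSE]
  if (nrow(dropped)) {
    for (i in seq_len(nrow(dropped))) {
      cat(sprintf("  dropped %-24s %s\n", dropped$column[i], dropped$reason[i]))
    }
  }
  if (!is.null(x$selection)) {
    cat(sprintf("k selection: elbow = %d, silhouette = %d\n",
                x$selection$k_elbow, x$selection$k_silhouette))
  }
  for (k in names(x$attempts)) print(x$attempts[[k]])
  print(x)
  invisible(x)
}

#' @export
plot.season_states <- function(x, ...) {
  if (x$no_states) {
    graphics::plot.new()
    graphics::title("No seasonal states")
    return(invisible(x))
  }
  labs <- factor(x$labels_smoothed)
  graphics::par(mfrow = c(1 + !is.null(x$pca), 1), mar = c(4, 4, 2, 1))
  graphics::plot(seq_len(365), as.integer(labs), type = "s",
                 xlab = "ordinal day", ylab = "state", yaxt = "n",
                 main = "Smoothed daily state assignment")
  graphics::axis(2, at = seq_along(levels(labs)), labels = levels(labs))
  graphics::abline(v = x$calendar$transitions$day, lty = 2)
  if (!is.null(x$pca)) {
    st <- factor(x$pca$scores$state)
    graphics::plot(x$pca$scores$PC1, x$pca$scores$PC2, col = as.integer(st),
                   pch = 16, cex = 0.6, xlab = "PC1", ylab = "PC2",
                   main = "Daily space use by state")
    graphics::legend("topright", legend = levels(st),
                     col = seq_along(levels(st)), pch = 16, bty = "n")
  }
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}
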