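## Season delineation from the daily space-use matrix: noisy-variable
## screening (HINoV), ANOVA screening, k selection (elbow + silhouette),
## bootstrap-Jaccard cluster stability, moving-window smoothing, run-based
## transition dating, and PCA characterization.

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the contingency-table closed form. Invariant to relabeling;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)           # both partitions trivial
  (sij - expected) / (mx - expected)
}

# deterministic k-means: fixed derived seed, multiple random restarts
seeded_kmeans <- function(m, k, seed, nstart = 10) {
  set.seed(seed)
  stats::kmeans(m, centers = k, nstart = nstart, iter.max = 50)
}

#' HINoV screen for noisy clustering variables
#'
#' Heuristic identification of noisy variables: each variable is clustered
#' alone (k-means, `k_probe` clusters, fixed seed); the topri score of a
#' variable is the row sum of adjusted Rand indices between its partition and
#' every other variable's partition. Variables that carry shared cluster
#' structure score high; pure-noise variables score near zero. The report
#' flags (but does not yet remove) the low-information group below the
#' largest gap in the sorted topri sequence.
#'
#' @param dm a `daily_matrix` (or plain numeric matrix) with >= 3 usable
#'   variables.
#' @param k_probe probe cluster count (>= 2, default 2).
#' @param seed RNG seed for the single-variable k-means fits.
#' @param min_gap smallest topri gap treated as a real signal/noise split.
#'   Adjusted Rand has a natural scale (independent partitions score ~0,
#'   shared structure ~0.5+), so when every variable is noise the sorted
#'   topri sequence shows only small sampling gaps; requiring the largest
#'   gap to exceed `min_gap` (default 0.5) keeps the screen from cutting an
#'   all-noise profile down to an arbitrary survivor.
#' @return a `hinov_report`: `ari` (pairwise adjusted-Rand matrix), `topri`
#'   (named, sorted decreasing), `flagged` (low-information variables),
#'   `excluded` (variables with too few distinct values to probe).
#' @export
hinov_screen <- function(dm, k_probe = 2, seed = 1, min_gap = 0.5) {
  m <- if (inherits(dm, "daily_matrix")) retained_matrix(dm) else as.matrix(dm)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  stopifnot(k_probe >= 2)
  usable <- vapply(seq_len(ncol(m)),
                   function(j) length(unique(m[, j])) >= k_probe, TRUE)
  excluded <- colnames(m)[!usable]
  m <- m[, usable, drop = FALSE]
  p <- ncol(m)
  if (p < 3) {
    stop_ecoseasons("HINoV needs at least 3 usable variables", "invalid_config_error")
  }
  parts <- lapply(seq_len(p), function(j) {
    seeded_kmeans(m[, j, drop = FALSE], k_probe, derive_seed(seed, j))$cluster
  })
  ari <- matrix(1, p, p, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ari[i, j] <- ari[j, i] <- adjusted_rand(parts[[i]], parts[[j]])
    }
  }
  topri <- sort(rowSums(ari) - 1, decreasing = TRUE)  # self excluded
  gaps <- -diff(topri)
  flagged <- if (length(gaps) && max(gaps) > min_gap) {
    cut <- which.max(gaps)
    names(topri)[(cut + 1):length(topri)]
  } else {
    character(0)
  }
  structure(list(ari = ari, topri = topri, flagged = flagged,
                 excluded = excluded, k_probe = k_probe),
            class = "hinov_report")
}

#' @export
print.hinov_report <- function(x, ...) {
  cat(sprintf("HINoV screen (probe k = %d)\n", x$k_probe))
  for (v in names(x$topri)) {
    cat(sprintf("  %-24s topri = %6.2f%s\n", v, x$topri[v],
                if (v %in% x$flagged) "  [flagged noisy]" else ""))
  }
  if (length(x$excluded)) {
    cat("Excluded (too few distinct values):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ANOVA variable screen against a candidate partition
#'
#' One-way ANOVA of each variable across the groups of a candidate day
#' partition. Under the default mode, variables whose distributions do NOT
#' differ across groups (p >= alpha) are listed for removal — they carry no
#' information about the candidate structure. The literal alternative
#' (removing the variables that DO differ) is available as
#' `mode = "remove_significant"`; see the methods vignette for why the
#' default is the information-preserving reading.
#'
#' @param dm a `daily_matrix` or numeric matrix.
#' @param assignment candidate group label per (non-missing) day; >= 2 groups.
#' @param alpha significance level (default 0.05).
#' @param mode `"remove_nonsignificant"` (default) or `"remove_significant"`.
#' @param adjust multiplicity adjustment applied across the tested variables
#'   before comparing to `alpha` (any [stats::p.adjust()] method; default
#'   `"none"`, the single-test rule). The pipeline uses `"holm"` so that an
#'   aseasonal population does not retain lucky variables at the family
#'   level.
#' @return list with `p_values` (named, unadjusted), `p_adjusted`, `remove`
#'   (variables listed for removal), `skipped` (variables untestable because
#'   some group had < 2 observations), and `mode`.
#' @export
anova_screen <- function(dm, assignment, alpha = 0.05,
                         mode = c("remove_nonsignificant",
                                  "remove_significant"),
                         adjust = "none") {
  mode <- match.arg(mode)
  m <- if (inherits(dm, "daily_matrix")) retained_matrix(dm) else as.matrix(dm)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  stopifnot(length(assignment) == nrow(m), length(unique(assignment)) >= 2)
  g <- factor(assignment)
  p_values <- rep(NA_real_, ncol(m))
  names(p_values) <- colnames(m)
  skipped <- character(0)
  for (j in seq_len(ncol(m))) {
    if (any(table(g) < 2)) {
      skipped <- c(skipped, colnames(m)[j])
      next
    }
    fit <- stats::aov(m[, j] ~ g)
    p_values[j] <- summary(fit)[[1]][["Pr(>F)"]][1]
  }
  p_adj <- stats::p.adjust(p_values, method = adjust)
  remove <- if (mode == "remove_significant") {
    names(p_values)[!is.na(p_adj) & p_adj < alpha]
  } else {
    names(p_values)[!is.na(p_adj) & p_adj >= alpha]
  }
  list(p_values = p_values, p_adjusted = p_adj, remove = remove,
       skipped = skipped, mode = mode)
}

# mean silhouette width for a k-means assignment, from a precomputed
# distance matrix ("manual programming": no cluster-package dependency)
mean_silhouette <- function(dmat, cluster) {
  n <- length(cluster)
  ks <- sort(unique(cluster))
  if (length(ks) < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    a <- if (sum(own) > 1) sum(dmat[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(ks[ks != cluster[i]], function(kk) {
      mean(dmat[i, cluster == kk])
    }, 0))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Choose the number of clusters
#'
#' Computes the within-cluster sum of squares curve over `k_min:k_max`
#' (deterministic seeded k-means) plus k = 1 for the elbow. The elbow k
#' maximizes the second difference of the WSS curve; the silhouette k
#' maximizes the mean silhouette width. Full curves are returned for audit.
#'
#' @param dm a `daily_matrix` or numeric matrix with >= `k_max` complete rows.
#' @param k_min,k_max candidate range (defaults 2 and 8).
#' @param seed RNG seed.
#' @return list with `k_elbow`, `k_silhouette`, `wss` (named, from k = 1),
#'   `sil` (named, from `k_min`).
#' @export
select_k <- function(dm, k_min = 2, k_max = 8, seed = 1) {
  m <- if (inherits(dm, "daily_matrix")) retained_matrix(dm) else as.matrix(dm)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (k_max > nrow(m)) {
    stop_ecoseasons("k_max exceeds the number of complete days",
                    "invalid_range_error")
  }
  stopifnot(k_min >= 2, k_max >= k_min)
  ks <- k_min:k_max
  wss <- c(sum(scale(m, scale = FALSE)^2),
           vapply(ks, function(k) {
             seeded_kmeans(m, k, derive_seed(seed, k))$tot.withinss
           }, 0))
  names(wss) <- c(1, ks)
  dmat <- as.matrix(stats::dist(m))
  sil <- vapply(ks, function(k) {
    mean_silhouette(dmat, seeded_kmeans(m, k, derive_seed(seed, k))$cluster)
  }, 0)
  names(sil) <- ks
  d2 <- wss[as.character(ks - 1)] - 2 * wss[as.character(ks)] +
    c(wss[as.character(ks[-length(ks)] + 1)], NA)
  k_elbow <- ks[which.max(d2[seq_len(length(ks) - 1)])]
  if (length(ks) == 1) k_elbow <- ks
  list(k_elbow = unname(k_elbow),
       k_silhouette = unname(ks[which.max(sil)]),
       wss = wss, sil = sil)
}

# Jaccard similarity of two index sets
jaccard_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Bootstrap-Jaccard stability of a k-means clustering
#'
#' For each of `n_seeds` random-number seeds: fit a reference k-means, then
#' for each of `B` bootstrap resamples of the days (matrix rows, with
#' replacement) refit k-means on the resample and match every reference
#' cluster to the resample cluster maximizing Jaccard similarity over the
#' days present in the resample. The per-cluster mean Jaccard over replicates
#' is compared against gamma: instability of ANY cluster under ANY seed voids
#' the clustering. When stable, the first seed's day assignment is returned.
#'
#' @param dm a `daily_matrix` or numeric matrix.
#' @param k number of clusters (>= 2).
#' @param B bootstrap replicates per seed (default 5000; 200 is a practical
#'   test profile).
#' @param n_seeds number of outer seeds (default 10).
#' @param gamma per-cluster mean-Jaccard stability threshold (default 0.75).
#' @param seed master seed from which the outer seeds are derived.
#' @param nstart_boot k-means restarts per bootstrap refit.
#' @return a `stability_report`: `jaccard` (n_seeds x k matrix of mean
#'   Jaccard), `stable` (verdict), `assignment` (day labels from the first
#'   seed when stable, else NULL), `k`, `B`, `gamma`, `retries` (empty-cluster
#'   refit retries used).
#' @export
stable_kmeans <- function(dm, k, B = 5000, n_seeds = 10, gamma = 0.75,
                          seed = 1, nstart_boot = 5) {
  m <- if (inherits(dm, "daily_matrix")) retained_matrix(dm) else as.matrix(dm)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  stopifnot(k >= 2, B >= 1)
  n <- nrow(m)
  jac <- matrix(NA_real_, n_seeds, k)
  assignment <- NULL
  retries <- 0L
  unstable <- FALSE
  for (s in seq_len(n_seeds)) {
    sseed <- derive_seed(seed, s)
    ref <- seeded_kmeans(m, k, sseed)
    if (s == 1) assignment <- ref$cluster
    ref_members <- split(seq_len(n), ref$cluster)
    sums <- numeric(k); cnts <- numeric(k)
    set.seed(derive_seed(sseed, 1e6))
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- NULL
      for (try in seq_len(10L)) {
        fit <- tryCatch(stats::kmeans(m[idx, , drop = FALSE], centers = k,
                                      nstart = nstart_boot, iter.max = 50),
                        error = function(e) NULL)
        if (!is.null(fit) && length(unique(fit$cluster)) == k) break
        retries <- retries + 1L
        fit <- NULL
      }
      present <- unique(idx)
      if (is.null(fit)) {                  # unmatched clusters score 0
        for (c1 in seq_len(k)) {
          if (length(intersect(ref_members[[c1]], present))) {
            sums[c1] <- sums[c1] + 0; cnts[c1] <- cnts[c1] + 1
          }
        }
        next
      }
      # day -> bootstrap cluster (first occurrence; duplicated rows are
      # identical so k-means assigns them identically)
      boot_members <- split(idx, fit$cluster)
      boot_members <- lapply(boot_members, unique)
      for (c1 in seq_len(k)) {
        ref_set <- intersect(ref_members[[c1]], present)
        if (!length(ref_set)) next        # cluster absent from resample
        best <- max(vapply(boot_members, jaccard_sets, 0, a = ref_set))
        sums[c1] <- sums[c1] + best
        cnts[c1] <- cnts[c1] + 1
      }
    }
    jac[s, ] <- ifelse(cnts > 0, sums / cnts, 0)
    if (any(jac[s, ] < gamma)) {          # verdict already decided
      unstable <- TRUE
      break
    }
  }
  structure(list(jaccard = jac, stable = !unstable,
                 assignment = if (!unstable) assignment else NULL,
                 k = k, B = B, gamma = gamma, retries = retries),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Bootstrap stability: k = %d, B = %d, gamma = %.2f -> %s\n",
              x$k, x$B, x$gamma, if (x$stable) "STABLE" else "UNSTABLE"))
  done <- which(rowSums(!is.na(x$jaccard)) > 0)
  for (s in done) {
    cat(sprintf("  seed %2d: %s\n", s,
                paste(sprintf("%.3f", x$jaccard[s, ]), collapse = "  ")))
  }
  invisible(x)
}

#' Smooth daily cluster assignments with a circular moving-window mode
#'
#' Each ordinal day receives the modal label of the `window`-day window
#' centered on it, wrapping across the year boundary. Ties break in favor of
#' the day's own raw label, then toward the smallest label.
#'
#' @param day_labels label vector over the full 365-day circle.
#' @param window odd window width in days (default 5).
#' @return smoothed label vector, same length.
#' @export
smooth_assignments <- function(day_labels, window = 5) {
  n <- length(day_labels)
  if (window %% 2 == 0) {
    stop_ecoseasons("window must be odd (center undefined otherwise)",
                    "invalid_config_error")
  }
  half <- (window - 1) / 2
  offsets <- -half:half
  chr <- as.character(day_labels)
  out <- vapply(seq_len(n), function(d) {
    w <- chr[wrap_day(d + offsets, n)]
    tab <- table(w)
    winners <- names(tab)[tab == max(tab)]
    if (chr[d] %in% winners) chr[d] else sort(winners)[1]
  }, "")
  if (is.integer(day_labels)) as.integer(out)
  else if (is.numeric(day_labels)) as.numeric(out)
  else out
}

# maximal circular runs of a label sequence: data.frame(label, start, end,
# length) in circular order, starting at a run boundary
circular_runs <- function(labels) {
  n <- length(labels)
  if (length(unique(labels)) == 1) {
    return(data.frame(label = labels[1], start = 1L, end = n,
                      length = n, stringsAsFactors = FALSE))
  }
  anchor <- which(labels != labels[wrap_day(seq_len(n) - 1, n)])[1]
  rot <- labels[wrap_day(anchor + seq_len(n) - 1L, n)]
  r <- rle(as.vector(rot))
  start_rot <- cumsum(c(1L, utils::head(r$lengths, -1)))
  data.frame(label = r$values,
             start = wrap_day(anchor + start_rot - 1L, n),
             end = wrap_day(anchor + start_rot + r$lengths - 2L, n),
             length = r$lengths, stringsAsFactors = FALSE)
}

# days of a circular window start..end inclusive
circular_span <- function(start, end, n = 365) {
  if (start <= end) start:end else c(start:n, 1:end)
}

#' Transition dates from smoothed daily assignments
#'
#' For each boundary between consecutive (circular) label regimes: scanning
#' chronologically, date A is the first day starting `run_length` consecutive
#' days in the new label; scanning reverse-chronologically, date B is the day
#' after the last day ending `run_length` consecutive days in the old label.
#' The transition is the circular midpoint of A and B rounded half-up, and is
#' the first day of the new state. Label regimes shorter than `run_length`
#' cannot host a transition; they are merged into their larger neighbor with
#' a message.
#'
#' @param smoothed_labels label vector over the full 365-day circle with >= 2
#'   distinct labels.
#' @param run_length required consecutive-day run (default 8).
#' @param provenance carried into the calendar.
#' @return a [season_calendar()].
#' @export
transition_dates <- function(smoothed_labels, run_length = 8,
                             provenance = list()) {
  n <- length(smoothed_labels)
  if (length(unique(smoothed_labels)) < 2) {
    stop_ecoseasons("need at least 2 distinct labels to date transitions",
                    "invalid_config_error")
  }
  original <- smoothed_labels             # scans see the unmerged sequence
  merged <- smoothed_labels
  runs <- circular_runs(merged)
  # merge regimes too short to satisfy the run rule into the larger neighbor;
  # merging fixes the final state structure only — the A/B scans below run on
  # the original labels, whose stray days the run rule is designed to skip
  repeat {
    if (nrow(runs) <= 1) {
      stop_ecoseasons("no regime of at least run_length days remains",
                      "invalid_config_error")
    }
    short <- which(runs$length < run_length)
    if (!length(short)) break
    i <- short[which.min(runs$length[short])]
    nb_prev <- wrap_day(i - 1, nrow(runs)); nb_next <- wrap_day(i + 1, nrow(runs))
    into <- if (runs$length[nb_prev] >= runs$length[nb_next]) nb_prev else nb_next
    message(sprintf(
      "regime '%s' (%d day(s)) shorter than run_length; merged into '%s'",
      runs$label[i], runs$length[i], runs$label[into]))
    merged[circular_span(runs$start[i], runs$end[i], n)] <- runs$label[into]
    if (length(unique(merged)) < 2) {
      stop_ecoseasons("merging left a single regime; no transitions exist",
                      "invalid_config_error")
    }
    runs <- circular_runs(merged)
  }
  m <- nrow(runs)
  trans_day <- integer(m)
  for (b in seq_len(m)) {                 # boundary into regime b
    old <- wrap_day(b - 1, m)
    window <- c(circular_span(runs$start[old], runs$end[old], n),
                circular_span(runs$start[b], runs$end[b], n))
    new_lab <- runs$label[b]; old_lab <- runs$label[old]
    A <- NA_integer_
    for (d in window) {
      if (all(original[wrap_day(d + 0:(run_length - 1), n)] == new_lab)) {
        A <- d; break
      }
    }
    B <- NA_integer_
    for (d in rev(window)) {
      if (all(original[wrap_day(d - (run_length - 1):0, n)] == old_lab)) {
        B <- wrap_day(d + 1, n); break
      }
    }
    if (is.na(A) || is.na(B)) {
      stop_ecoseasons(sprintf(
        "no %d-day run found around the boundary into '%s'",
        run_length, new_lab), "invalid_config_error")
    }
    trans_day[b] <- circ_midpoint(A, B, n)
  }
  states <- data.frame(label = runs$label,
                       start_day = trans_day,
                       end_day = wrap_day(trans_day[wrap_day(seq_len(m) + 1, m)] - 1, n),
                       stringsAsFactors = FALSE)
  season_calendar(states, provenance = c(provenance,
                                         list(run_length = run_length)))
}

#' PCA characterization of the daily matrix by state
#'
#' Principal components of the retained (transformed, hence zero-mean) daily
#' matrix, with per-day scores labeled by calendar state. Reports the percent
#' variance of components 1-2 — the analog of "the first two components
#' described X% of variation".
#'
#' @param dm a `daily_matrix` (transformed).
#' @param calendar a `season_calendar` labeling the days.
#' @return a `pca_summary`: `loadings` (p x 2, unit-norm columns),
#'   `pct_variance` (all components), `scores` (day, state, PC1, PC2), or
#'   NULL with a message when < 2 variables remain.
#' @export
characterize_pca <- function(dm, calendar) {
  m <- retained_matrix(dm, complete = FALSE)
  days <- which(!dm$missing & stats::complete.cases(m))
  m <- m[days, , drop = FALSE]
  if (ncol(m) < 2) {
    message("fewer than 2 retained variables; PCA skipped")
    return(NULL)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation[, 1:2, drop = FALSE],
                 pct_variance = pct,
                 scores = data.frame(day = days,
                                     state = state_of_day(calendar, days),
                                     PC1 = pc$x[, 1],
                                     PC2 = if (ncol(pc$x) > 1) pc$x[, 2] else 0)),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat(sprintf("PCA: components 1-2 describe %.1f%% of variation (%.1f%% + %.1f%%)\n",
              sum(x$pct_variance[1:2]), x$pct_variance[1], x$pct_variance[2]))
  print(round(x$loadings, 3))
  invisible(x)
}
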