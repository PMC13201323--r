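# Season clustering machinery: adjusted Rand, HINoV, ANOVA screen, k
# selection, bootstrap stability, smoothing, transition dating, PCA.

# --- adjusted Rand ----------------------------------------------------------

test_that("adjusted Rand is label-invariant and matches the mclust oracle", {
  set.seed(2)
  a <- sample(1:3, 80, replace = TRUE)
  b <- sample(1:4, 80, replace = TRUE)
  expect_equal(adjusted_rand(a, a), 1)
  relab <- c(9, 7, 8)[a]                  # random relabeling of cluster ids
  expect_equal(adjusted_rand(a, relab), 1)
  for (i in 1:20) {
    set.seed(i)
    x <- sample(1:3, 60, replace = TRUE)
    y <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand(x, y), mclust::adjustedRandIndex(x, y),
                 tolerance = 1e-12)
  }
})

# --- HINoV ------------------------------------------------------------------

test_that("HINoV gives a pure-noise variable the minimum topri", {
  set.seed(13)
  sig <- c(stats::rnorm(30, 0), stats::rnorm(30, 6))
  m <- cbind(s1 = scale(sig + stats::rnorm(60, 0, 0.3))[, 1],
             s2 = scale(sig + stats::rnorm(60, 0, 0.3))[, 1],
             noise = scale(stats::runif(60))[, 1])
  rep <- hinov_screen(m, k_probe = 2, seed = 1)
  expect_equal(names(which.min(rep$topri)), "noise")
  expect_true("noise" %in% rep$flagged)
})

test_that("identical variables share identical topri", {
  set.seed(14)
  v <- stats::rnorm(60)
  m <- cbind(a = v, b = v, c = v)
  rep <- hinov_screen(m, k_probe = 2, seed = 1)
  expect_true(max(rep$topri) - min(rep$topri) < 1e-12)
  expect_length(rep$flagged, 0)
})

# --- ANOVA screen -----------------------------------------------------------

test_that("ANOVA screen applies the literal rule under remove_significant", {
  set.seed(15)
  g <- rep(1:2, each = 30)
  m <- cbind(flat = stats::rnorm(60),
             sep = stats::rnorm(60) + 10 * (g - 1))
  lit <- anova_screen(m, g, mode = "remove_significant")
  expect_true("sep" %in% lit$remove)      # separated by 10 SDs -> listed
  expect_false("flat" %in% lit$remove)    # identical across groups
  expect_gt(lit$p_values["flat"], 0.05)
  none <- anova_screen(m, g, alpha = 0, mode = "remove_significant")
  expect_length(none$remove, 0)           # alpha = 0: nothing ever listed
})

test_that("default ANOVA mode removes uninformative variables instead", {
  set.seed(16)
  g <- rep(1:2, each = 30)
  m <- cbind(flat = stats::rnorm(60),
             sep = stats::rnorm(60) + 10 * (g - 1))
  def <- anova_screen(m, g)
  expect_true("flat" %in% def$remove)
  expect_false("sep" %in% def$remove)
})

# --- k selection ------------------------------------------------------------

make_blobs <- function(k, n_per, sep, p = 2, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(k * p), k, p)
  centers <- sep * centers / sqrt(rowSums(centers^2))
  do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(stats::rnorm(n_per * p), n_per, p) +
      matrix(centers[i, ], n_per, p, byrow = TRUE)
  }))
}

test_that("both selectors find two well-separated blobs", {
  m <- make_blobs(2, 60, sep = 10, seed = 3)
  sel <- select_k(m, k_min = 2, k_max = 6, seed = 1)
  expect_equal(sel$k_elbow, 2)
  expect_equal(sel$k_silhouette, 2)
  expect_true(all(sel$sil >= -1 & sel$sil <= 1))
})

test_that("silhouette finds three equidistant blobs", {
  m <- rbind(matrix(stats::rnorm(80), 40, 2) + 10,
             matrix(stats::rnorm(80), 40, 2),
             cbind(stats::rnorm(40) + 10, stats::rnorm(40)))
  sel <- select_k(m, k_min = 2, k_max = 6, seed = 2)
  expect_equal(sel$k_silhouette, 3)
})

test_that("manual silhouette matches the cluster-package oracle", {
  m <- make_blobs(3, 30, sep = 4, seed = 5)
  for (k in 2:4) {
    cl <- ecoseasons:::seeded_kmeans(m, k, 9)$cluster
    mine <- ecoseasons:::mean_silhouette(as.matrix(stats::dist(m)), cl)
    oracle <- mean(cluster::silhouette(cl, stats::dist(m))[, 3])
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
  expect_error(select_k(m[1:5, ], k_max = 8), class = "invalid_range_error")
})

# --- bootstrap stability ----------------------------------------------------

test_that("Jaccard similarity of sets behaves at the extremes", {
  expect_equal(ecoseasons:::jaccard_sets(1:5, 1:5), 1)
  expect_equal(ecoseasons:::jaccard_sets(1:5, 6:10), 0)
  expect_equal(ecoseasons:::jaccard_sets(1:4, 3:6), 1 / 3)
})

test_that("well-separated blobs are bootstrap-stable", {
  m <- make_blobs(2, 100, sep = 20, seed = 6)
  rep <- stable_kmeans(m, 2, B = 200, n_seeds = 3, seed = 1)
  expect_true(rep$stable)
  expect_true(all(rep$jaccard > 0.95, na.rm = TRUE))
  expect_true(all(rep$jaccard >= 0 & rep$jaccard <= 1, na.rm = TRUE))
  expect_length(rep$assignment, 200)
})

test_that("a single spherical Gaussian forced to k = 2 is unstable", {
  unstable <- 0
  for (r in 1:10) {
    set.seed(100 + r)
    m <- matrix(stats::rnorm(200 * 4), 200, 4)
    rep <- stable_kmeans(m, 2, B = 200, n_seeds = 3, seed = r)
    if (!rep$stable) unstable <- unstable + 1
  }
  expect_gte(unstable, 9)
})

test_that("stability does not decrease with blob separation", {
  seps <- c(1, 4, 12)
  mean_min <- vapply(seps, function(sep) {
    mins <- vapply(1:8, function(r) {
      m <- make_blobs(2, 50, sep = sep, seed = 200 + r)
      rep <- stable_kmeans(m, 2, B = 50, n_seeds = 2, seed = r)
      min(rep$jaccard, na.rm = TRUE)
    }, 0)
    mean(mins)
  }, 0)
  expect_true(all(diff(mean_min) >= -0.02))  # non-decreasing up to MC noise
})

# --- smoothing --------------------------------------------------------------

smooth_oracle <- function(labels, window) {
  n <- length(labels)
  half <- (window - 1) / 2
  out <- labels
  for (d in seq_len(n)) {
    w <- labels[((d - 1 + seq(-half, half)) %% n) + 1]
    tab <- sort(table(w), decreasing = TRUE)
    winners <- names(tab)[tab == max(tab)]
    out[d] <- if (as.character(labels[d]) %in% winners) labels[d]
              else sort(winners)[1]
  }
  out
}

test_that("moving-window mode smoothing matches a brute-force oracle", {
  expect_equal(smooth_assignments(rep("A", 365)), rep("A", 365))
  blip <- rep("A", 20); blip[10] <- "B"
  expect_equal(smooth_assignments(blip, 5), rep("A", 20))
  for (r in 1:200) {
    set.seed(r)
    n <- sample(10:30, 1)
    labs <- sample(c("A", "B"), n, replace = TRUE)
    expect_identical(smooth_assignments(labs, 5), smooth_oracle(labs, 5))
  }
  expect_error(smooth_assignments(rep("A", 10), window = 4),
               class = "invalid_config_error")
})

test_that("a 2-2 window tie keeps the day's own label", {
  # window c(A, A, ?, B, B): whatever the center's own label, it wins the tie
  labs <- c(rep("A", 10), "A", "A", "A", "B", "B", rep("B", 10))
  boundary_day <- 13                       # window A A A B B -> A majority
  labs2 <- labs
  labs2[13] <- "B"                         # window A A B B B -> B majority
  s1 <- smooth_assignments(labs, 5)
  s2 <- smooth_assignments(labs2, 5)
  expect_equal(s1[13], "A")
  expect_equal(s2[13], "B")
  # construct an exact 2-2 tie with a 3-label window
  tie <- c(rep("C", 6), "A", "A", "B", "B", "B", "A", rep("C", 6))
  sm <- smooth_assignments(tie, 5)
  # day 10 window: A B B B A -> B wins; day 8 window: C A A B B -> tie A/B,
  # own label A retained
  expect_equal(sm[8], "A")
})

# --- transition dating ------------------------------------------------------

# independent reimplementation of the documented rule, plain loops
transition_oracle <- function(labels, run_length = 8) {
  n <- length(labels)
  runs_of <- function(lab) {
    # all start positions of run_length-day pure runs of lab
    ok <- logical(n)
    for (d in seq_len(n)) {
      ok[d] <- all(labels[((d - 1 + 0:(run_length - 1)) %% n) + 1] == lab)
    }
    which(ok)
  }
  # final regimes after iterative merging of short ones
  lab <- labels
  repeat {
    runs <- ecoseasons:::circular_runs(lab)
    if (nrow(runs) <= 1) return(NULL)
    short <- which(runs$length < run_length)
    if (!length(short)) break
    i <- short[which.min(runs$length[short])]
    np <- ((i - 2) %% nrow(runs)) + 1
    nn <- (i %% nrow(runs)) + 1
    into <- if (runs$length[np] >= runs$length[nn]) np else nn
    days <- if (runs$start[i] <= runs$end[i]) runs$start[i]:runs$end[i]
            else c(runs$start[i]:n, 1:runs$end[i])
    lab[days] <- runs$label[into]
    if (length(unique(lab)) < 2) return(NULL)
  }
  runs <- ecoseasons:::circular_runs(lab)
  m <- nrow(runs)
  out <- integer(m)
  for (b in seq_len(m)) {
    old <- ((b - 2) %% m) + 1
    span <- function(i) if (runs$start[i] <= runs$end[i])
      runs$start[i]:runs$end[i] else c(runs$start[i]:n, 1:runs$end[i])
    window <- c(span(old), span(b))
    starts_new <- intersect(window, runs_of(runs$label[b]))
    A <- starts_new[1]
    ends_old <- intersect(window, (runs_of(runs$label[old]) + run_length - 2) %% n + 1)
    B <- (rev(ends_old)[1] %% n) + 1
    out[b] <- circ_midpoint(A, B, n)
  }
  list(days = out, labels = runs$label)
}

test_that("a clean step change dates the transition exactly", {
  labs <- rep("W", 365)
  labs[100:299] <- "S"
  cal <- transition_dates(labs, run_length = 8)
  expect_equal(sort(cal$transitions$day), c(100, 300))
  expect_equal(state_of_day(cal, 100), "S")
  expect_equal(state_of_day(cal, 299), "S")
  expect_equal(state_of_day(cal, 300), "W")
  durs <- ((cal$states$end_day - cal$states$start_day) %% 365) + 1
  expect_equal(sum(durs), 365)
})

test_that("an isolated blip near a boundary follows the A/B scan rule", {
  # ... A A B A B B B B B B ... : forward scan skips the isolated B
  labs <- rep("A", 365)
  labs[120:365] <- "B"
  labs[117] <- "B"                        # isolated B inside the A regime
  suppressMessages(cal <- transition_dates(labs, run_length = 8))
  # forward scan: the isolated B at 117 cannot start an 8-run, so A = 120;
  # backward scan: the last 8-day all-A run ends at 116 (117 breaks longer
  # ones), so the candidate is 117; midpoint of 120 and 117 rounds to 119.
  # The other boundary is clean: both scans give day 1.
  expect_equal(nrow(cal$states), 2)
  expect_equal(sort(cal$transitions$day), c(1, 119))
})

test_that("transition dating matches the independent oracle on random seasons", {
  mismatches <- 0
  for (r in 1:300) {
    set.seed(400 + r)
    # random 2-4 blocks with lengths >= 8 plus occasional 1-2 day blips
    n_blocks <- sample(c(2, 4), 1)
    lens <- as.vector(stats::rmultinom(1, 365 - 8 * n_blocks,
                                       rep(1, n_blocks))) + 8
    labs <- rep(rep(c("A", "B"), length.out = n_blocks), lens)
    nb <- sample(0:3, 1)
    if (nb > 0) {
      pos <- sample(365, nb)
      labs[pos] <- sample(c("A", "B"), nb, replace = TRUE)
    }
    got <- tryCatch(suppressMessages(transition_dates(labs, run_length = 8)),
                    error = function(e) NULL)
    want <- tryCatch(transition_oracle(labs, run_length = 8),
                     error = function(e) NULL)
    if (is.null(got) != is.null(want)) {
      mismatches <- mismatches + 1
    } else if (!is.null(got)) {
      if (!setequal(got$transitions$day, want$days)) mismatches <- mismatches + 1
    }
  }
  expect_equal(mismatches, 0)
})

test_that("regimes shorter than the run length are merged with a message", {
  labs <- rep("A", 365)
  labs[100:299] <- "B"
  labs[350:355] <- "C"                    # 6-day regime, cannot host a run
  expect_message(cal <- transition_dates(labs, run_length = 8), "merged")
  expect_equal(sort(unique(cal$states$label)), c("A", "B"))
  expect_error(transition_dates(rep(c("A", "B"), length.out = 20),
                                run_length = 8),
               class = "invalid_config_error")
})

# --- PCA characterization ---------------------------------------------------

test_that("PCA summary respects rank and ordering invariants", {
  sp <- small_population()
  fit <- suppressMessages(season_states(sp$dm, B = 50, n_seeds = 2, seed = 3))
  expect_false(fit$no_states)
  pca <- fit$pca
  expect_true(all(diff(pca$pct_variance) <= 1e-9))
  expect_true(all(abs(colSums(pca$loadings^2) - 1) < 1e-9))
  expect_true(all(pca$scores$state %in% fit$calendar$states$label))
  # two-variable matrix: two components explain everything
  two <- sp$dm
  two$meta$retained <- two$meta$column %in% c("step_length", "slope")
  p2 <- characterize_pca(two, fit$calendar)
  expect_equal(sum(p2$pct_variance[1:2]), 100, tolerance = 1e-9)
})

test_that("isotropic noise spreads variance evenly across components", {
  shares <- vapply(1:20, function(r) {
    set.seed(600 + r)
    m <- matrix(stats::rnorm(365 * 6), 365, 6)
    pc <- stats::prcomp(m)
    100 * pc$sdev[1]^2 / sum(pc$sdev^2)
  }, 0)
  # component-1 share close to 1/6 with the usual O(n^-1/2) excess
  expect_lt(mean(shares), 100 / 6 * (1 + 6 / sqrt(365)))
  expect_gt(mean(shares), 100 / 6)
})

# --- end-to-end determinism -------------------------------------------------

test_that("season_states is deterministic under identical seeds", {
  sp <- small_population()
  a <- suppressMessages(season_states(sp$dm, B = 30, n_seeds = 2, seed = 5))
  b <- suppressMessages(season_states(sp$dm, B = 30, n_seeds = 2, seed = 5))
  expect_identical(a$calendar$states, b$calendar$states)
  expect_identical(a$labels_smoothed, b$labels_smoothed)
})
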