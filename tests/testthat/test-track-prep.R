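# Track preparation: boundary-day filtering, greedy resampling, step
# metrics, covariate extraction, the daily matrix, transforms, and the
# collinearity filter — each against its stated oracle.

test_that("boundary-day exclusion implements the 7-day rule", {
  t0 <- as.POSIXct("2021-06-01 00:00:00", tz = "UTC")
  tr <- data.frame(individual_id = "a", timestamp = t0 + (0:29) * 86400,
                   x = 0, y = 0)
  out <- exclude_boundary_days(tr, "2021-06-01", "2021-06-30")
  expect_equal(nrow(out), 16)             # 30 days minus 7 at each end
  expect_identical(exclude_boundary_days(tr, "2021-06-01", "2021-06-30",
                                         buffer_days = 0), tr)
  expect_warning(exclude_boundary_days(tr, "2021-06-01", "2021-06-05"),
                 "empty")
})

test_that("boundary-day exclusion matches a per-fix date filter oracle", {
  set.seed(4)
  t0 <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")
  hours <- sort(stats::runif(200, 0, 24 * 120))
  tr <- data.frame(individual_id = "a", timestamp = t0 + hours * 3600,
                   x = stats::rnorm(200), y = stats::rnorm(200))
  cap <- as.Date("2021-01-10"); end <- as.Date("2021-04-01")
  out <- exclude_boundary_days(tr, cap, end, buffer_days = 7)
  d <- as.Date(tr$timestamp, tz = "UTC")
  oracle <- tr[d >= cap + 7 & d <= end - 7, ]
  rownames(oracle) <- NULL
  expect_identical(out, oracle)
})

test_that("greedy resampling reproduces hand-traced selections", {
  tr <- make_track(x = 1:6, y = rep(0, 6), hours = c(0, 4, 8, 12, 16, 24))
  out <- resample_track(tr, 12, 2)
  expect_equal(out$x, c(1, 4, 6))         # fixes at 0, 12, 24 h
  tr2 <- make_track(x = 1:3, y = rep(0, 3), hours = c(0, 15, 27))
  out2 <- resample_track(tr2, 12, 2)
  expect_equal(out2$x, 1:3)               # chain restart at 15, then 27
  reg <- make_track(x = 1:5, y = rep(0, 5), hours = seq(0, 48, by = 12))
  expect_identical(resample_track(reg, 12, 2), reg)
})

test_that("resampling is idempotent and rejects unsorted input", {
  set.seed(8)
  hours <- sort(stats::runif(300, 0, 24 * 40))
  tr <- make_track(x = seq_along(hours), y = rep(0, length(hours)),
                   hours = hours)
  once <- resample_track(tr, 12, 2)
  twice <- resample_track(once, 12, 2)
  expect_identical(once, twice)
  gaps <- diff(as.numeric(once$timestamp) / 3600)
  expect_true(all(gaps >= 10 | gaps > 14))
  bad <- tr[c(2, 1, 3), ]
  expect_error(resample_track(bad, 12, 2), class = "ordering_error")
})

test_that("step metrics match elementary geometry", {
  tr <- make_track(x = c(0, 3), y = c(0, 4))
  out <- compute_step_metrics(tr)
  expect_equal(out$step_length, c(NA, 5))
  col <- compute_step_metrics(make_track(x = c(0, 1, 2), y = c(0, 0, 0)))
  expect_equal(col$turning_angle, c(NA, NA, 0))
  left <- compute_step_metrics(make_track(x = c(0, 1, 1), y = c(0, 0, 1)))
  expect_equal(left$turning_angle, c(NA, NA, 90))
  dup <- compute_step_metrics(make_track(x = c(0, 1, 1, 2),
                                         y = c(0, 0, 0, 0)))
  expect_equal(dup$step_length, c(NA, 1, 0, 1))
  expect_true(is.na(dup$turning_angle[3]))
})

test_that("turning angles negate under time reversal", {
  set.seed(12)
  n <- 50
  tr <- make_track(x = cumsum(stats::rnorm(n)), y = cumsum(stats::rnorm(n)))
  fwd <- compute_step_metrics(tr)
  rev_tr <- tr[n:1, ]
  rev_tr$timestamp <- tr$timestamp        # restore increasing times
  bwd <- compute_step_metrics(rev_tr)
  # turn completed on arrival at fix i (vertex i-1) maps to vertex n-i+1,
  # stored on the reversed fix n-i+2
  for (i in 3:n) {
    expect_equal(bwd$turning_angle[n - i + 3], -fwd$turning_angle[i],
                 tolerance = 1e-9)
  }
})

test_that("covariate extraction equals a brute-force containment oracle", {
  ls <- tiny_landscape()
  g <- ls$grid
  set.seed(3)
  x <- stats::runif(100, g$xmin, g$xmax - 1e-9)
  y <- stats::runif(100, g$ymin + 1e-9, g$ymax)
  tr <- make_track(x = x, y = y)
  out <- extract_covariates(tr, ls)
  for (f in seq_len(100)) {
    hit <- NULL
    for (i in seq_len(g$n_rows)) {
      for (j in seq_len(g$n_cols)) {
        left <- g$xmin + (j - 1) * g$cell_size
        top <- g$ymax - (i - 1) * g$cell_size
        if (x[f] >= left && x[f] < left + g$cell_size &&
            y[f] <= top && y[f] > top - g$cell_size) {
          hit <- c(i, j); break
        }
      }
      if (!is.null(hit)) break
    }
    expect_equal(out$slope[f], ls$slope[hit[1], hit[2]])
    expect_equal(out$land_cover[f], ls$classes[ls$land_cover[hit[1], hit[2]]])
  }
  far <- make_track(x = g$xmax + 10, y = g$ymin - 10)
  expect_error(extract_covariates(far, ls), class = "out_of_bounds_error")
})

test_that("daily matrix equals a group-by oracle and handles Feb 29", {
  ls <- tiny_landscape()
  set.seed(5)
  n <- 400
  t0 <- as.POSIXct("2019-06-01 00:00:00", tz = "UTC")
  tr <- data.frame(
    individual_id = sample(c("a", "b"), n, replace = TRUE),
    timestamp = t0 + sort(stats::runif(n, 0, 500 * 86400)),
    x = stats::runif(n, ls$grid$xmin, ls$grid$xmax - 1),
    y = stats::runif(n, ls$grid$ymin + 1, ls$grid$ymax))
  tr <- tr[order(tr$individual_id, tr$timestamp), ]
  ann <- extract_covariates(compute_step_metrics(tr), ls)
  dm <- daily_population_matrix(ann)
  od <- ordinal_day(ann$timestamp)
  for (d in unique(od)) {
    rows <- ann[od == d, ]
    expect_equal(unname(dm$values[d, "slope"]), mean(rows$slope))
    expect_equal(unname(dm$values[d, "step_length"]),
                 if (all(is.na(rows$step_length))) NA_real_
                 else mean(rows$step_length, na.rm = TRUE))
    expect_equal(unname(dm$values[d, "lc_wetland"]),
                 mean(rows$land_cover == "wetland"))
  }
  # occupancy fractions sum to one on observed days
  occ <- dm$values[!dm$missing, grep("^lc_", colnames(dm$values))]
  expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
  # permutation invariance over fix order
  perm <- ann[sample(nrow(ann)), ]
  expect_equal(daily_population_matrix(perm)$values, dm$values)
  # Feb 29 2020 fixes land on ordinal day 59
  leap <- ann[1, ]
  leap$timestamp <- as.POSIXct("2020-02-29 12:00:00", tz = "UTC")
  dml <- daily_population_matrix(leap)
  expect_false(dml$missing[59])
  expect_equal(sum(!dml$missing), 1)
})

test_that("single- and two-fix days reduce to the fixes themselves", {
  ls <- tiny_landscape()
  tr <- make_track(x = c(200, 300, 500), y = c(200, 250, 400),
                   hours = c(0, 24, 25))
  ann <- extract_covariates(compute_step_metrics(tr), ls)
  dm <- daily_population_matrix(ann)
  d1 <- ordinal_day(ann$timestamp[1])
  expect_equal(unname(dm$values[d1, "slope"]), ann$slope[1])
  expect_equal(unname(dm$values[d1, paste0("lc_", ann$land_cover[1])]), 1)
  d2 <- ordinal_day(ann$timestamp[2])
  expect_equal(unname(dm$values[d2, "step_length"]),
               mean(ann$step_length[2:3]))   # two fixes, mean of their steps
})

test_that("column transforms symmetrize and standardize", {
  set.seed(6)
  vals <- cbind(sym = stats::rnorm(365),
                skewed = stats::rexp(365)^1.5,
                const = rep(2, 365))
  dm <- structure(list(values = vals, n_fixes = rep(1L, 365),
                       missing = rep(FALSE, 365),
                       meta = data.frame(column = colnames(vals),
                                         transform = "none", retained = TRUE,
                                         reason = "",
                                         stringsAsFactors = FALSE)),
                  class = "daily_matrix")
  out <- transform_columns(dm)
  expect_equal(out$meta$transform[1], "zscore")
  expect_equal(out$meta$transform[2], "sqrt+zscore")
  expect_gt(e1071::skewness(vals[, "skewed"]), 1)
  expect_lt(abs(e1071::skewness(sqrt(vals[, "skewed"]))),
            e1071::skewness(vals[, "skewed"]))
  expect_false(out$meta$retained[3])
  expect_match(out$meta$reason[3], "zero variance")
  for (j in 1:2) {
    expect_lt(abs(mean(out$values[, j])), 1e-9)
    expect_lt(abs(stats::sd(out$values[, j]) - 1), 1e-9)
  }
})

test_that("collinearity filter drops duplicates and follows the hand rule", {
  set.seed(5)
  base <- stats::rnorm(365)
  vals <- cbind(a = scale(base)[, 1], b = scale(base)[, 1],
                c = scale(stats::rnorm(365))[, 1])
  dm <- structure(list(values = vals, n_fixes = rep(1L, 365),
                       missing = rep(FALSE, 365),
                       meta = data.frame(column = colnames(vals),
                                         transform = "zscore",
                                         retained = TRUE, reason = "",
                                         stringsAsFactors = FALSE)),
                  class = "daily_matrix")
  out <- collinearity_filter(dm)
  expect_equal(sum(out$meta$retained[1:2]), 1)  # exactly one duplicate dropped
  expect_true(out$meta$retained[3])
  # independent noise columns survive
  set.seed(5)
  noise <- sapply(1:6, function(i) scale(stats::rnorm(365))[, 1])
  colnames(noise) <- letters[1:6]
  dmn <- structure(list(values = noise, n_fixes = rep(1L, 365),
                        missing = rep(FALSE, 365),
                        meta = data.frame(column = colnames(noise),
                                          transform = "zscore",
                                          retained = TRUE, reason = "",
                                          stringsAsFactors = FALSE)),
                   class = "daily_matrix")
  expect_lt(max(abs(stats::cor(noise)[upper.tri(diag(6))])), 0.70)
  outn <- collinearity_filter(dmn)
  expect_true(all(outn$meta$retained))
  # three mutually correlated columns: survivor matches the stated rule
  set.seed(9)
  z <- stats::rnorm(365)
  trio <- cbind(p = z + stats::rnorm(365, 0, 0.4),
                q = z + stats::rnorm(365, 0, 0.4),
                r = z + stats::rnorm(365, 0, 0.4))
  dmt <- structure(list(values = trio, n_fixes = rep(1L, 365),
                        missing = rep(FALSE, 365),
                        meta = data.frame(column = colnames(trio),
                                          transform = "zscore",
                                          retained = TRUE, reason = "",
                                          stringsAsFactors = FALSE)),
                   class = "daily_matrix")
  outt <- collinearity_filter(dmt)
  expect_equal(sum(outt$meta$retained), 1)
  # brute-force replication of the removal order
  keep <- 1:3
  repeat {
    r <- abs(stats::cor(trio[, keep, drop = FALSE])); diag(r) <- 0
    if (length(keep) < 2 || max(r) < 0.70) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    mac <- rowMeans(r)
    drop_local <- if (mac[worst[1]] > mac[worst[2]]) worst[1]
                  else if (mac[worst[2]] > mac[worst[1]]) worst[2]
                  else max(worst)
    keep <- keep[-drop_local]
  }
  expect_equal(which(outt$meta$retained), keep)
})
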