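## Synthetic landscape stacks: smoothed Gaussian random fields thresholded at
## class-quantile breakpoints, terrain derived from a generated elevation
## surface, and exact Euclidean distance layers. All layers share one grid in
## projected planar meters; matrices are stored row 1 = top (north).

#' Land-cover classes used throughout the package
#'
#' Boreal-transition classes typical of the western Lake Superior shoreline;
#' agriculture and grassland are folded into shrubland upstream of this
#' package, so they never appear as separate classes.
#'
#' @export
LAND_COVER_CLASSES <- c("open_water", "coniferous_forest", "deciduous_forest",
                        "mixed_forest", "shrubland", "wetland")

#' Default mainland land-cover composition
#'
#' Class proportions for the default simulated landscape (44% mixed forest,
#' 17% deciduous, 11% coniferous, 9% shrubland, 7% wetland, 5% open water;
#' remainder assigned to the largest class).
#'
#' @export
MAINLAND_PROPORTIONS <- c(mixed_forest = 0.44, deciduous_forest = 0.17,
                          coniferous_forest = 0.11, shrubland = 0.09,
                          wetland = 0.07, open_water = 0.05)

#' Grid specification for a landscape stack
#'
#' @param n_rows,n_cols grid dimensions in cells.
#' @param cell_size cell edge length in meters (default 30, matching common
#'   land-cover products).
#' @param xmin,ymin coordinates of the lower-left corner (projected meters).
#' @return a `grid_spec` list with derived extent fields.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 30, xmin = 0, ymin = 0) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, xmin = xmin, ymin = ymin,
                 xmax = xmin + n_cols * cell_size,
                 ymax = ymin + n_rows * cell_size),
            class = "grid_spec")
}

# smoothed standard-normal random field via separable Gaussian kernel
# smoothing matrices (row-stochastic, so edges are handled by renormalization)
gaussian_field <- function(n_rows, n_cols, range_cells = 8) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  smat <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-0.5 * (d / range_cells)^2)
    k[d > 3 * range_cells] <- 0
    k / rowSums(k)
  }
  f <- smat(n_rows) %*% z %*% t(smat(n_cols))
  (f - mean(f)) / stats::sd(f)
}

# exact Euclidean distance (m) from every cell center to the nearest source
# cell center; chunked to bound memory on large grids
distance_to_cells <- function(grid, src_rows, src_cols) {
  cs <- grid$cell_size
  sx <- grid$xmin + (src_cols - 0.5) * cs
  sy <- grid$ymax - (src_rows - 0.5) * cs
  n <- grid$n_rows * grid$n_cols
  ij <- arrayInd(seq_len(n), c(grid$n_rows, grid$n_cols))
  cx <- grid$xmin + (ij[, 2] - 0.5) * cs
  cy <- grid$ymax - (ij[, 1] - 0.5) * cs
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / max(1L, length(sx))))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(cx[s:e], sx, "-")^2 + outer(cy[s:e], sy, "-")^2
    out[s:e] <- sqrt(do.call(pmin, c(as.data.frame(d2), na.rm = FALSE)))
  }
  matrix(out, grid$n_rows, grid$n_cols)
}

# slope (degrees) and northness (cos aspect) from central differences of an
# elevation matrix; flat cells get northness 0
terrain_layers <- function(elev, cell_size) {
  nr <- nrow(elev); nc <- ncol(elev)
  pad_r <- elev[c(1, seq_len(nr), nr), ]
  pad_c <- elev[, c(1, seq_len(nc), nc)]
  # y axis points north = decreasing row index
  gy <- (pad_r[seq_len(nr), ] - pad_r[seq_len(nr) + 2L, ]) / (2 * cell_size)
  gx <- (pad_c[, seq_len(nc) + 2L] - pad_c[, seq_len(nc)]) / (2 * cell_size)
  g <- sqrt(gx^2 + gy^2)
  slope <- atan(g) * 180 / pi
  northness <- ifelse(g > 0, -gy / g, 0)
  list(slope = slope, northness = northness)
}

#' Generate a synthetic landscape stack
#'
#' Builds co-registered layers on one grid: categorical land cover (smoothed
#' Gaussian random field cut at class-quantile breakpoints, so realized class
#' fractions match the request by construction), slope and northness derived
#' from a generated elevation surface, and Euclidean distance-to-lake and
#' distance-to-road layers. The lake source is the open-water cell set (or the
#' western grid edge when the composition has no water); the road is one
#' meandering west-east polyline.
#'
#' @param class_proportions named numeric vector of target fractions over
#'   `LAND_COVER_CLASSES` (subset allowed); must be non-negative and sum to
#'   at most 1 — any remainder is assigned to the largest requested class.
#' @param grid a [grid_spec()].
#' @param seed integer RNG seed; the stack is fully reproducible given it.
#' @param patch_range correlation range of the class field, in cells.
#' @param relief_m total relief of the elevation surface in meters.
#' @return a `landscape_stack`: list with `grid`, `classes`, and matrices
#'   `land_cover` (integer codes into `classes`), `slope`, `northness`,
#'   `dist_lake`, `dist_road`.
#' @examples
#' ls <- make_landscape(MAINLAND_PROPORTIONS, grid_spec(60, 60), seed = 1)
#' landscape_class_fractions(ls)
#' @export
make_landscape <- function(class_proportions, grid, seed,
                           patch_range = 8, relief_m = 150) {
  stopifnot(inherits(grid, "grid_spec"))
  p <- class_proportions
  if (any(p < 0)) {
    stop_ecoseasons("class proportions must be non-negative",
                    "invalid_config_error")
  }
  if (is.null(names(p)) || !all(names(p) %in% LAND_COVER_CLASSES)) {
    stop_ecoseasons("class proportions must be named with known land-cover classes",
                    "invalid_config_error")
  }
  if (sum(p) > 1 + 1e-9) {
    stop_ecoseasons("class proportions must sum to at most 1",
                    "invalid_config_error")
  }
  rem <- 1 - sum(p)
  p[which.max(p)] <- p[which.max(p)] + rem
  p <- p[p > 0]
  n_cells <- grid$n_rows * grid$n_cols
  if (any(p * n_cells < 1)) {
    stop_ecoseasons("grid too small to realize every requested class",
                    "degenerate_landscape_error")
  }

  set.seed(derive_seed(seed, 1))
  f <- gaussian_field(grid$n_rows, grid$n_cols, patch_range)
  breaks <- stats::quantile(f, probs = cumsum(p) / sum(p), names = FALSE)
  breaks[length(breaks)] <- Inf
  codes_present <- match(names(p), LAND_COVER_CLASSES)
  lc <- matrix(codes_present[findInterval(f, c(-Inf, utils::head(breaks, -1)))],
               grid$n_rows, grid$n_cols)

  set.seed(derive_seed(seed, 2))
  elev <- gaussian_field(grid$n_rows, grid$n_cols, patch_range * 2) *
    (relief_m / 4)
  terr <- terrain_layers(elev, grid$cell_size)

  water <- which(lc == match("open_water", LAND_COVER_CLASSES),
                 arr.ind = TRUE)
  if (nrow(water) == 0) {                 # waterless composition: west edge
    water <- cbind(seq_len(grid$n_rows), 1L)
  }
  dist_lake <- distance_to_cells(grid, water[, 1], water[, 2])

  set.seed(derive_seed(seed, 3))
  drift <- cumsum(stats::rnorm(grid$n_cols, 0, 0.6))
  road_rows <- pmin(grid$n_rows, pmax(1L, round(grid$n_rows / 2 +
                                                  drift - mean(drift))))
  dist_road <- distance_to_cells(grid, road_rows, seq_len(grid$n_cols))

  structure(list(grid = grid, classes = LAND_COVER_CLASSES,
                 land_cover = lc, slope = terr$slope,
                 northness = terr$northness,
                 dist_lake = dist_lake, dist_road = dist_road,
                 seed = seed),
            class = "landscape_stack")
}

#' Realized land-cover class fractions
#'
#' @param landscape a `landscape_stack`.
#' @return named numeric vector over all classes (zeros for absent classes).
#' @export
landscape_class_fractions <- function(landscape) {
  stopifnot(inherits(landscape, "landscape_stack"))
  tab <- tabulate(landscape$land_cover, nbins = length(landscape$classes))
  stats::setNames(tab / sum(tab), landscape$classes)
}

# cell indices for projected coordinates under the half-open convention:
# a cell owns its left and top edges, i.e. x in [left, right), y in (bottom,
# top]. NA outside the extent.
cell_index <- function(grid, x, y) {
  j <- 1L + floor((x - grid$xmin) / grid$cell_size)
  i <- 1L + floor((grid$ymax - y) / grid$cell_size)
  bad <- x < grid$xmin | x >= grid$xmax | y <= grid$ymin | y > grid$ymax
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  cbind(row = as.integer(i), col = as.integer(j))
}

# covariate data.frame at coordinates; errors listing out-of-bounds fixes
landscape_values_at <- function(landscape, x, y) {
  idx <- cell_index(landscape$grid, x, y)
  if (anyNA(idx[, 1])) {
    bad <- which(is.na(idx[, 1]))
    stop_ecoseasons(sprintf(
      "%d location(s) outside the landscape extent (first offenders: %s)",
      length(bad), paste(utils::head(bad, 5), collapse = ", ")),
      "out_of_bounds_error")
  }
  lin <- idx[, 1] + (idx[, 2] - 1L) * landscape$grid$n_rows
  data.frame(
    land_cover = landscape$classes[landscape$land_cover[lin]],
    slope = landscape$slope[lin],
    northness = landscape$northness[lin],
    dist_lake = landscape$dist_lake[lin],
    dist_road = landscape$dist_road[lin],
    stringsAsFactors = FALSE)
}

#' @export
print.landscape_stack <- function(x, ...) {
  g <- x$grid
  cat(sprintf("Landscape stack: %d x %d cells at %g m (extent %g-%g, %g-%g)\n",
              g$n_rows, g$n_cols, g$cell_size, g$xmin, g$xmax, g$ymin, g$ymax))
  fr <- landscape_class_fractions(x)
  cat("Land cover:\n")
  for (cl in names(fr)) cat(sprintf("  %-18s %5.1f%%\n", cl, 100 * fr[cl]))
  invisible(x)
}

#' @export
plot.landscape_stack <- function(x, ...) {
  lc <- x$land_cover[rev(seq_len(nrow(x$land_cover))), , drop = FALSE]
  graphics::image(t(lc), col = grDevices::hcl.colors(6, "Terrain"),
                  axes = FALSE, main = "Land cover", ...)
  invisible(x)
}

#' Write a landscape stack as plain-text layers
#'
#' One whitespace-delimited matrix per layer plus a JSON header with the grid,
#' class legend (integer code to label), and generator seed. The inverse of
#' [read_landscape()].
#'
#' @param landscape a `landscape_stack`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- list(grid = landscape$grid[c("n_rows", "n_cols", "cell_size",
                                      "xmin", "ymin")],
              classes = landscape$classes, seed = landscape$seed,
              layers = c("land_cover", "slope", "northness",
                         "dist_lake", "dist_road"))
  jsonlite::write_json(hdr, file.path(dir, "landscape.json"),
                       auto_unbox = TRUE, digits = NA)
  for (ly in hdr$layers) {
    utils::write.table(landscape[[ly]], file.path(dir, paste0(ly, ".txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a landscape stack written by [write_landscape()]
#'
#' @param dir directory containing `landscape.json` and the layer matrices.
#' @return a `landscape_stack`.
#' @export
read_landscape <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "landscape.json"),
                             simplifyVector = TRUE)
  g <- do.call(grid_spec, as.list(hdr$grid))
  layers <- lapply(hdr$layers, function(ly) {
    unname(as.matrix(utils::read.table(file.path(dir, paste0(ly, ".txt")))))
  })
  names(layers) <- hdr$layers
  layers$land_cover <- matrix(as.integer(layers$land_cover),
                              g$n_rows, g$n_cols)
  structure(c(list(grid = g, classes = hdr$classes), layers,
              list(seed = hdr$seed)),
            class = "landscape_stack")
}
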