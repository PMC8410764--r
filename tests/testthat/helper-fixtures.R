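# Small test lake: radius 200 m, 20 m deep paraboloid basin, 10-m cells.
tiny_scenario <- function(max_depth = 20, radius = 200) {
  lake_scenario(
    name = "TEST", max_depth = max_depth, surface_area = pi * radius^2,
    macrophyte_profile = data.frame(
      depth_min = 0, depth_max = 3, coverage_min = 10, coverage_max = 20,
      height_min = 20, height_max = 60))
}

tiny_lake <- function(...) make_lake(tiny_scenario(...))

# Build a q-position tibble from parallel vectors.
qp <- function(tag = "F1", t, x = NA_real_, y = NA_real_,
               depth = NA_real_, interpolated = FALSE) {
  n <- length(t)
  tibble::tibble(
    tag_id = tag,
    interval_start = as.POSIXct(t, tz = "UTC"),
    x = rep_len(x, n), y = rep_len(y, n), depth = rep_len(depth, n),
    n_fixes = ifelse(is.na(rep_len(x, n)), 0L, 1L),
    n_depth_fixes = ifelse(is.na(rep_len(depth, n)), 0L, 1L),
    interpolated = rep_len(interpolated, n))
}

# Build a raw-fix tibble.
fx <- function(tag = "F1", t, x = NA_real_, y = NA_real_,
               depth = NA_real_) {
  n <- length(t)
  tibble::tibble(
    tag_id = tag, timestamp = as.POSIXct(t, tz = "UTC"),
    x = rep_len(x, n), y = rep_len(y, n), depth = rep_len(depth, n),
    has_xy = !is.na(rep_len(x, n)))
}

# A twilight table with fixed civil dawn 05:00 / dusk 21:00 UTC.
flat_twilight <- function(dates) {
  dates <- as.Date(dates)
  tibble::tibble(
    date = dates,
    dawn = as.POSIXct(dates, tz = "UTC") + 5 * 3600,
    dusk = as.POSIXct(dates, tz = "UTC") + 21 * 3600)
}

# Independent dense-grid oracle for the horizontal 95% KUD: direct
# summation of bivariate Gaussian kernels over every in-lake cell centre,
# no separability, no bounding box.
oracle_kud <- function(px, py, lake, h = 50, cell = 10, level = 0.95) {
  half <- floor(lake$radius / cell)
  g <- expand.grid(x = seq(-half, half) * cell, y = seq(-half, half) * cell)
  g <- g[g$x^2 + g$y^2 < lake$radius^2, ]
  dens <- 0
  for (i in seq_along(px))
    dens <- dens + exp(-((g$x - px[i])^2 + (g$y - py[i])^2) / (2 * h^2))
  p <- sort(dens / sum(dens), decreasing = TRUE)
  n <- which(cumsum(p) >= level)[1]
  n * cell^2 / 1e4
}

# Independent oracle for the 1-D 95% highest-density kernel length.
oracle_vks <- function(depths, bw = 0.4, level = 0.95, step = 0.05) {
  grid <- seq(min(depths) - 4 * bw, max(depths) + 4 * bw, by = step)
  dens <- vapply(grid, function(g) sum(dnorm(g, depths, bw)), numeric(1))
  p <- sort(dens / sum(dens), decreasing = TRUE)
  n <- which(cumsum(p) >= level)[1]
  n * step
}

# q-positions for one fish-day at given coordinates, with alternating
# day/night labels so the >12/>12 availability rule passes for n >= 26.
kud_day <- function(x, y) {
  n <- length(x)
  tibble::tibble(x = x, y = y,
                 diel = rep_len(c("day", "night"), n),
                 interval_start = as.POSIXct("2015-06-01", tz = "UTC") +
                   900 * seq_len(n))
}
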