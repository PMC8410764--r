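#' Describe a study-lake scenario
#'
#' A scenario bundles the morphometry and vegetation structure of one lake
#' together with its seasonal covariates, and is the single input from which
#' [make_lake()], [make_macrophyte_survey()], [make_temperature()] and the
#' trajectory simulator derive everything else.
#'
#' @param name Lake label.
#' @param max_depth Maximum depth (m), attained at the lake centre.
#' @param surface_area Lake surface area (m^2).
#' @param raster_cell Bathymetry/KUD raster cell size (m).
#' @param macrophyte_profile A data frame with columns `depth_min`,
#'   `depth_max` (m), `coverage_min`, `coverage_max` (percent) and
#'   `height_min`, `height_max` (cm) giving the colonized depth band(s) and
#'   the uniform ranges vegetation is drawn from.
#' @param thermocline A function of `date` (class `Date`) returning the
#'   thermocline depth in m.
#' @return An object of class `lake_scenario`.
#' @seealso [scenario_hsc()], [scenario_lsc()] for the two built-in presets
#'   contrasting high and low structural complexity.
#' @export
lake_scenario <- function(name, max_depth, surface_area, raster_cell = 10,
                          macrophyte_profile,
                          thermocline = function(date) 8) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(max_depth) || max_depth <= 0)
    stop("`max_depth` must be a positive depth in m", call. = FALSE)
  if (!is.numeric(surface_area) || surface_area <= 0)
    stop("`surface_area` must be a positive area in m^2", call. = FALSE)
  stopifnot(is.data.frame(macrophyte_profile))
  need <- c("depth_min", "depth_max", "coverage_min", "coverage_max",
            "height_min", "height_max")
  if (!all(need %in% names(macrophyte_profile)))
    stop("`macrophyte_profile` must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  with(macrophyte_profile, {
    if (any(coverage_min < 0 | coverage_max > 100 | coverage_min > coverage_max))
      stop("coverage ranges must lie within [0, 100]", call. = FALSE)
    if (any(height_min < 0 | height_min > height_max))
      stop("height ranges must be non-negative", call. = FALSE)
  })
  structure(
    list(name = name, max_depth = max_depth, surface_area = surface_area,
         raster_cell = raster_cell, macrophyte_profile = macrophyte_profile,
         thermocline = thermocline),
    class = "lake_scenario")
}

#' Built-in lake presets: high and low structural complexity
#'
#' `scenario_hsc()` is a 25-m deep, 252-ha basin with dense macrophytes
#' (60-91% cover) colonizing inshore areas to 12 m. `scenario_lsc()` is a
#' 75-m deep, 311-ha basin with sparse vegetation (0.1-1.6% cover) restricted
#' to 0-3 m. Both share a thermocline declining from ~6.5 m in early June to
#' ~9.5 m by late September.
#'
#' @return A `lake_scenario`.
#' @export
scenario_hsc <- function() {
  lake_scenario(
    name = "HSC", max_depth = 25, surface_area = 2.52e6,
    macrophyte_profile = data.frame(
      depth_min = 0, depth_max = 12,
      coverage_min = 60, coverage_max = 91,
      height_min = 50, height_max = 200),
    thermocline = seasonal_thermocline())
}

#' @rdname scenario_hsc
#' @export
scenario_lsc <- function() {
  lake_scenario(
    name = "LSC", max_depth = 75, surface_area = 3.11e6,
    macrophyte_profile = data.frame(
      depth_min = 0, depth_max = 3,
      coverage_min = 0.1, coverage_max = 1.6,
      height_min = 10, height_max = 150),
    thermocline = seasonal_thermocline())
}

# Thermocline deepening linearly from 6.5 m (1 June) to 9.5 m (30 Sept).
seasonal_thermocline <- function(start = 6.5, end = 9.5) {
  d0 <- as.Date("2015-06-01")
  d1 <- as.Date("2015-09-30")
  function(date) {
    f <- as.numeric(as.Date(date) - d0) / as.numeric(d1 - d0)
    f <- pmin(pmax(f, 0), 1)
    start + f * (end - start)
  }
}

#' Build a bathymetric grid for a lake scenario
#'
#' Constructs a radially symmetric (paraboloid) basin on a square raster:
#' bottom depth at distance r from the centre is
#' `max_depth * (1 - (r/R)^2)` inside the shoreline radius
#' `R = sqrt(surface_area / pi)` and zero outside. The deepest cell (the
#' centre cell) equals `max_depth` exactly, and the shoreline polygon is the
#' circle of radius R. Construction is deterministic; `seed` is accepted for
#' interface uniformity with the other generators.
#'
#' @param scenario A [lake_scenario()].
#' @param seed Ignored (construction is deterministic).
#' @return A `lake_grid` with fields `name`, `cell` (m), `max_depth`,
#'   `radius`, `xc`/`yc` (cell-centre coordinates), `depth`
#'   (matrix, `depth[i, j]` at `(xc[i], yc[j])`), and `shoreline`
#'   (two-column vertex matrix).
#' @export
make_lake <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "lake_scenario"))
  R <- sqrt(scenario$surface_area / pi)
  cell <- scenario$raster_cell
  half <- ceiling(R / cell)
  xc <- seq(-half, half) * cell   # centre cell exactly at the origin
  yc <- xc
  r2 <- outer(xc^2, yc^2, "+")
  depth <- scenario$max_depth * pmax(1 - r2 / R^2, 0)
  ang <- seq(0, 2 * pi, length.out = 257L)[-257L]
  shoreline <- cbind(x = R * cos(ang), y = R * sin(ang))
  structure(
    list(name = scenario$name, cell = cell, max_depth = scenario$max_depth,
         radius = R, xc = xc, yc = yc, depth = depth, shoreline = shoreline,
         scenario = scenario),
    class = "lake_grid")
}

#' @export
print.lake_grid <- function(x, ...) {
  cat(sprintf(
    "<lake_grid '%s'>  %.0f x %.0f cells of %g m, max depth %g m, radius %.0f m\n",
    x$name, length(x$xc), length(x$yc), x$cell, x$max_depth, x$radius))
  invisible(x)
}

#' Bottom depth and shoreline membership
#'
#' `bottom_depth()` evaluates the basin's bottom depth (m) at planar
#' coordinates; positions beyond the shoreline return `NA`. `in_lake()`
#' tests whether positions lie inside the shoreline polygon, optionally
#' buffered outward.
#'
#' @param lake A `lake_grid`.
#' @param x,y Planar coordinates (m), vectorized.
#' @param buffer Outward buffer (m) applied to the shoreline for `in_lake()`.
#' @return Numeric depths (m) or a logical vector.
#' @export
bottom_depth <- function(lake, x, y) {
  stopifnot(inherits(lake, "lake_grid"))
  r <- sqrt(x^2 + y^2)
  d <- lake$max_depth * (1 - (r / lake$radius)^2)
  d[r >= lake$radius] <- NA_real_
  d
}

#' @rdname bottom_depth
#' @export
in_lake <- function(lake, x, y, buffer = 0) {
  stopifnot(inherits(lake, "lake_grid"))
  sqrt(x^2 + y^2) <= lake$radius + buffer
}

#' Write a bathymetry grid as an ESRI ASCII raster
#'
#' Plain-text export of the `depth` matrix in the standard ESRI ASCII grid
#' layout (rows from north to south).
#'
#' @param lake A `lake_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(lake, path) {
  stopifnot(inherits(lake, "lake_grid"))
  nr <- length(lake$yc); nc <- length(lake$xc)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %g", min(lake$xc) - lake$cell / 2),
    sprintf("yllcorner %g", min(lake$yc) - lake$cell / 2),
    sprintf("cellsize %g", lake$cell),
    "NODATA_value -9999")
  # depth[i, j] is at (xc[i], yc[j]); ASCII rows run top (max y) to bottom
  rows <- vapply(rev(seq_len(nr)), function(j)
    paste(format(lake$depth[, j], trim = TRUE), collapse = " "), character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
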