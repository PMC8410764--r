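#' Simulate a SCUBA macrophyte transect survey
#'
#' Generates one quadrat per 1-m depth interval (0-12 m) per transect. In
#' depth bins inside the scenario's colonized band, total quadrat coverage is
#' drawn uniformly within the scenario's stated coverage range and split
#' across the common macrophyte taxa; per-species heights are drawn uniformly
#' within the stated height range. Bins outside the colonized band have zero
#' coverage.
#'
#' @param lake A `lake_grid` (provides the scenario when `scenario` is NULL).
#' @param scenario A [lake_scenario()]; defaults to the one the lake was
#'   built from.
#' @param period Survey-period label (e.g. `"June"`, `"September"`).
#' @param n_transects Number of transects (>= 1).
#' @param seed Integer seed.
#' @param max_bin Deepest surveyed interval (m).
#' @return A tibble of transect quadrats: `lake`, `period`, `transect_id`,
#'   `depth_bin` (lower edge, m), `species`, `coverage` (percent),
#'   `height_min`, `height_max` (cm).
#' @export
make_macrophyte_survey <- function(lake, scenario = NULL, period = "June",
                                   n_transects = 25, seed = 1L,
                                   max_bin = 12L) {
  if (is.null(scenario)) scenario <- lake$scenario
  stopifnot(inherits(scenario, "lake_scenario"))
  if (n_transects < 1) stop("`n_transects` must be >= 1", call. = FALSE)
  taxa <- c("Potamogeton pectinatus", "Myriophyllum spicatum", "Chara sp.")
  prof <- scenario$macrophyte_profile
  set.seed(seed)
  rows <- list()
  for (tr in seq_len(n_transects)) {
    for (bin in seq_len(max_bin) - 1L) {
      band <- prof[prof$depth_min <= bin & prof$depth_max > bin, , drop = FALSE]
      if (nrow(band) == 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          lake = scenario$name, period = period,
          transect_id = sprintf("T%02d", tr), depth_bin = bin,
          species = NA_character_, coverage = 0,
          height_min = 0, height_max = 0)
        next
      }
      band <- band[1, ]
      total <- runif(1, band$coverage_min, band$coverage_max)
      w <- runif(length(taxa))
      cov <- total * w / sum(w)
      hmin <- runif(length(taxa), band$height_min,
                    (band$height_min + band$height_max) / 2)
      hmax <- runif(length(taxa), hmin, band$height_max)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        lake = scenario$name, period = period,
        transect_id = sprintf("T%02d", tr), depth_bin = bin,
        species = taxa, coverage = cov,
        height_min = hmin, height_max = hmax)
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate temperature-logger records
#'
#' Emulates logger ropes at fixed depths (1-m spacing to 13 m plus one at
#' 20 m) at two stations per lake, recording hourly. The water column follows
#' a logistic thermocline profile: warm epilimnion cooling seasonally, cold
#' hypolimnion near 6 degrees C.
#'
#' @param scenario A [lake_scenario()] (supplies the thermocline depth).
#' @param dates A vector of `Date`s to cover.
#' @param surface_temp Function of `Date` giving epilimnion temperature
#'   (degrees C).
#' @param noise_sd Measurement noise SD (degrees C).
#' @param seed Integer seed.
#' @return A tibble: `logger_id`, `timestamp` (UTC), `depth` (m),
#'   `temp` (degrees C).
#' @export
make_temperature <- function(scenario, dates,
                             surface_temp = function(d) {
                               doy <- as.integer(format(as.Date(d), "%j"))
                               16 + 6 * sin(2 * pi * (doy - 110) / 365)
                             },
                             noise_sd = 0.1, seed = 1L) {
  stopifnot(inherits(scenario, "lake_scenario"))
  depths <- c(0:13, 20)
  stations <- c("A", "B")
  hours <- 0:23
  grid <- expand.grid(date = as.Date(dates), hour = hours, depth = depths,
                      station = stations, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  tc <- scenario$thermocline(grid$date)
  ts <- surface_temp(grid$date)
  temp <- 6 + (ts - 6) / (1 + exp((grid$depth - tc) / 1.2)) +
    rnorm(nrow(grid), 0, noise_sd)
  tibble::tibble(
    logger_id = paste0(scenario$name, "_", grid$station, "_",
                       grid$depth, "m"),
    timestamp = as.POSIXct(grid$date, tz = "UTC") + grid$hour * 3600,
    depth = grid$depth, temp = temp)
}

#' Civil-twilight table for a span of dates
#'
#' Deterministic dawn/dusk clock times from a standard solar-geometry
#' approximation (civil twilight: sun 6 degrees below the horizon) at a
#' given latitude, expressed in UTC.
#'
#' @param dates A vector of `Date`s.
#' @param lat Latitude (degrees N).
#' @param lon Longitude (degrees E), used only as a mean-time offset.
#' @return A tibble: `date`, `dawn`, `dusk` (POSIXct UTC).
#' @export
make_twilight <- function(dates, lat = 50.5, lon = 13.8) {
  dates <- as.Date(dates)
  doy <- as.integer(format(dates, "%j"))
  decl <- 23.44 * sin(2 * pi * (doy - 80) / 365) * pi / 180
  latr <- lat * pi / 180
  cosH <- (sin(-6 * pi / 180) - sin(latr) * sin(decl)) /
    (cos(latr) * cos(decl))
  cosH <- pmin(pmax(cosH, -1), 1)
  H <- acos(cosH) * 12 / pi          # half day length in hours
  noon <- 12 - lon / 15              # local solar noon in UTC hours
  tibble::tibble(
    date = dates,
    dawn = as.POSIXct(dates, tz = "UTC") + (noon - H) * 3600,
    dusk = as.POSIXct(dates, tz = "UTC") + (noon + H) * 3600)
}
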