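#' Simulate a true fish trajectory
#'
#' Generates the true (unobserved) movement path of one fish on a regular
#' time step: an Ornstein-Uhlenbeck station-keeping walk for ambush fish, a
#' correlated random walk for cruising fish, with a reflective shoreline
#' boundary and an autoregressive depth process pulled toward either the
#' local bottom or the thermocline (see [movement_params()]). Depth never
#' exceeds the local bottom depth.
#'
#' @param lake A `lake_grid` from [make_lake()].
#' @param fish A [fish_spec()]; its `home_center` must lie inside the lake.
#' @param start,end POSIXct (UTC) span; positions are generated at
#'   `start, start + step, ...` up to but excluding `end`.
#' @param step Time step (s); must divide the observation burst interval.
#' @param params Movement parameters from [movement_params()].
#' @param seed Integer seed; identical seeds give identical tracks.
#' @return A tibble with columns `tag_id`, `time`, `x`, `y`, `depth`.
#' @export
simulate_track <- function(lake, fish, start, end, step = 25,
                           params = movement_params(fish$movement_mode),
                           seed = 1L) {
  stopifnot(inherits(lake, "lake_grid"), inherits(fish, "fish_spec"))
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (end <= start) stop("`end` must be after `start`", call. = FALSE)
  hc <- fish$home_center
  if (!in_lake(lake, hc[1], hc[2]))
    stop("home_center lies outside the lake", call. = FALSE)
  n <- as.integer(round(as.numeric(end - start, units = "secs") / step))
  times <- start + step * (seq_len(n) - 1)
  thermo <- lake$scenario$thermocline(as.Date(times))
  thermo <- rep_len(thermo, n)
  set.seed(seed)
  m <- cpp_simulate_track(
    n, step, as.integer(fish$movement_mode == "cruise"),
    hc[1], hc[2], hc[1], hc[2],
    params$revert, params$sigma, params$speed, params$speed_sdlog,
    params$turn_sd, params$depth_k, params$depth_sd, params$benthic_offset,
    params$pelagic_switch, params$pelagic_return,
    thermo, lake$max_depth, lake$radius)
  tibble::tibble(tag_id = fish$tag_id, time = times,
                 x = m[, 1], y = m[, 2], depth = m[, 3])
}

#' Observe a true trajectory through the telemetry system
#'
#' Thins a true trajectory to one candidate transmission per burst interval,
#' applies detection, positioning, gap, noise and sensor-ceiling processes of
#' an [observation_model()], and returns the raw position-estimate table the
#' processing pipeline starts from. Rows without a positionable fix carry a
#' depth reading only (`has_xy = FALSE`, `x`/`y` = `NA`).
#'
#' @param truth A trajectory from [simulate_track()] (one or several tags);
#'   its time step must divide the burst interval.
#' @param model An [observation_model()].
#' @param seed Integer seed.
#' @return A tibble with columns `tag_id`, `timestamp`, `x`, `y`, `depth`,
#'   `has_xy`, sorted by tag and time.
#' @export
observe_track <- function(truth, model = observation_model(), seed = 1L) {
  stopifnot(inherits(model, "observation_model"))
  need <- c("tag_id", "time", "x", "y", "depth")
  stopifnot(all(need %in% names(truth)))
  t0 <- min(truth$time)
  secs <- as.numeric(truth$time - t0, units = "secs")
  on_burst <- secs %% model$burst_interval == 0
  tr <- truth[on_burst, , drop = FALSE]
  secs <- secs[on_burst]
  set.seed(seed)
  p_det <- model$detect_prob(tr$depth, secs)
  # hourly dead zones, drawn independently per tag and clock hour
  if (model$gap_prob > 0) {
    hr <- match(tr$tag_id, unique(tr$tag_id)) * 2^30 + secs %/% 3600
    uh <- unique(hr)
    dead <- runif(length(uh)) < model$gap_prob
    p_det <- p_det * !dead[match(hr, uh)]
  }
  detected <- runif(nrow(tr)) < p_det
  tr <- tr[detected, , drop = FALSE]
  secs <- secs[detected]
  has_xy <- runif(nrow(tr)) < model$position_prob(tr$depth, secs)
  x <- ifelse(has_xy, tr$x + rnorm(nrow(tr), 0, model$xy_noise_sd), NA_real_)
  y <- ifelse(has_xy, tr$y + rnorm(nrow(tr), 0, model$xy_noise_sd), NA_real_)
  depth <- pmax(0, tr$depth + rnorm(nrow(tr), 0, model$depth_noise_sd))
  depth <- pmin(depth, model$depth_sensor_max)
  tibble::tibble(tag_id = tr$tag_id, timestamp = tr$time,
                 x = x, y = y, depth = depth, has_xy = has_xy)
}
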