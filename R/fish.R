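#' Describe a tagged fish
#'
#' @param tag_id Tag label.
#' @param body_length Total length (cm).
#' @param body_mass Mass (kg).
#' @param lake Lake label.
#' @param movement_mode `"ambush"` (station-keeping around a home centre) or
#'   `"cruise"` (extensive correlated random-walk search).
#' @param home_center Numeric `c(x, y)` home centre (m).
#' @param true_LR True littoral reliance, a fraction in `[0, 1]`, used by the
#'   isotope generator.
#' @param ages Age (years) at capture.
#' @param true_lengths_at_age Strictly increasing true lengths (cm) at each
#'   annulus, used by the scale generator.
#' @return An object of class `fish_spec`.
#' @export
fish_spec <- function(tag_id, body_length, body_mass = NA_real_,
                      lake = NA_character_,
                      movement_mode = c("ambush", "cruise"),
                      home_center = c(0, 0), true_LR = 0.7,
                      ages = NULL, true_lengths_at_age = NULL) {
  movement_mode <- match.arg(movement_mode)
  if (!is.numeric(body_length) || body_length <= 0)
    stop("`body_length` must be positive (cm)", call. = FALSE)
  if (!is.numeric(true_LR) || true_LR < 0 || true_LR > 1)
    stop("`true_LR` must lie in [0, 1]", call. = FALSE)
  if (!is.null(true_lengths_at_age) &&
      any(diff(true_lengths_at_age) <= 0))
    stop("`true_lengths_at_age` must be strictly increasing", call. = FALSE)
  structure(
    list(tag_id = as.character(tag_id), body_length = body_length,
         body_mass = body_mass, lake = lake, movement_mode = movement_mode,
         home_center = home_center, true_LR = true_LR,
         ages = ages %||% length(true_lengths_at_age),
         true_lengths_at_age = true_lengths_at_age),
    class = "fish_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Telemetry observation model
#'
#' Describes how the acoustic system samples a true trajectory: one candidate
#' transmission every `burst_interval` seconds; each is detected (yielding a
#' depth reading, which needs a single receiver) with probability
#' `detect_prob`, and a detected transmission additionally yields a planar
#' position (which needs three receivers) with probability `position_prob`.
#' Detected coordinates receive independent Gaussian noise, and reported
#' depth is clamped at the sensor ceiling `depth_sensor_max`. `gap_prob`
#' makes whole clock hours silent (no detections at all), emulating the
#' correlated dead zones seen in real coverage.
#'
#' @param burst_interval Transmission interval (s).
#' @param detect_prob Either a constant in `[0, 1]` or a
#'   `function(depth, time_s)` returning detection probabilities.
#' @param position_prob Constant or `function(depth, time_s)`: probability a
#'   detected transmission is positionable in x/y.
#' @param xy_noise_sd Positional noise SD (m).
#' @param depth_noise_sd Depth noise SD (m).
#' @param depth_sensor_max Depth-sensor ceiling (m); deeper true depths are
#'   reported at this value.
#' @param gap_prob Probability that any given clock hour is a dead zone.
#' @return An object of class `observation_model`.
#' @export
observation_model <- function(burst_interval = 25,
                              detect_prob = function(depth, time_s)
                                0.85 * exp(-depth / 30),
                              position_prob = function(depth, time_s)
                                0.5 * exp(-depth / 15),
                              xy_noise_sd = 3, depth_noise_sd = 0.1,
                              depth_sensor_max = 35, gap_prob = 0.15) {
  if (!is.numeric(burst_interval) || burst_interval <= 0)
    stop("`burst_interval` must be positive (s)", call. = FALSE)
  as_pfun <- function(p, what) {
    if (is.function(p)) return(p)
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("`", what, "` must be a probability or a function", call. = FALSE)
    force(p)
    function(depth, time_s) rep_len(p, length(depth))
  }
  if (any(c(xy_noise_sd, depth_noise_sd) < 0))
    stop("noise SDs must be >= 0", call. = FALSE)
  structure(
    list(burst_interval = burst_interval,
         detect_prob = as_pfun(detect_prob, "detect_prob"),
         position_prob = as_pfun(position_prob, "position_prob"),
         xy_noise_sd = xy_noise_sd, depth_noise_sd = depth_noise_sd,
         depth_sensor_max = depth_sensor_max, gap_prob = gap_prob),
    class = "observation_model")
}

#' Movement-parameter presets for the trajectory simulator
#'
#' Ambush fish follow an Ornstein-Uhlenbeck mean-reverting walk around their
#' home centre (stationary positional SD `sigma / sqrt(2 * revert)`, about
#' 20 m at the defaults) with depth pulled toward the local bottom. Cruising
#' fish follow a correlated random walk with wrapped-normal turning angles at
#' a target speed, and switch stochastically between a benthic depth target
#' (bottom minus `benthic_offset`) and a pelagic target at the thermocline.
#'
#' @param mode `"ambush"` or `"cruise"`.
#' @param ... Named overrides of individual parameters.
#' @return A named list of movement parameters: `revert` (1/s), `sigma`
#'   (m s^-1/2), `speed` (m/s), `speed_sdlog`, `turn_sd` (rad per step),
#'   `depth_k` (1/s), `depth_sd` (m s^-1/2), `benthic_offset` (m),
#'   `pelagic_switch`, `pelagic_return` (1/s).
#' @export
movement_params <- function(mode = c("ambush", "cruise"), ...) {
  mode <- match.arg(mode)
  p <- if (mode == "ambush") {
    list(revert = 3e-4, sigma = 0.5, speed = 0, speed_sdlog = 0,
         turn_sd = 0, depth_k = 0.01, depth_sd = 0.01,
         benthic_offset = 1, pelagic_switch = 0, pelagic_return = 0)
  } else {
    list(revert = 0, sigma = 0, speed = 0.3, speed_sdlog = 0.3,
         turn_sd = 0.4, depth_k = 0.01, depth_sd = 0.02,
         benthic_offset = 1,
         pelagic_switch = 0.1 / 3600, pelagic_return = 0.3 / 3600)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown movement parameters: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  p[names(over)] <- over
  p
}
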