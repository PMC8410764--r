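#' Label q-positions as daytime or night-time
#'
#' Daytime is the interval from one hour after civil dawn to one hour before
#' civil dusk; everything else is night. The label is decided at the
#' q-position interval midpoint.
#'
#' @param qpos A q-position tibble.
#' @param twilight A twilight table (`date`, `dawn`, `dusk`), e.g. from
#'   [make_twilight()]; it must cover every date present.
#' @return `qpos` with `date` (UTC calendar day of the interval midpoint)
#'   and `diel` (`"day"`/`"night"`) columns.
#' @export
split_diel <- function(qpos, twilight) {
  mid <- qpos$interval_start + Q_INTERVAL / 2
  date <- as.Date(mid, tz = "UTC")
  hit <- match(date, as.Date(twilight$date))
  if (anyNA(hit))
    stop("twilight table missing date(s): ",
         paste(unique(date[is.na(hit)]), collapse = ", "), call. = FALSE)
  day_start <- twilight$dawn[hit] + 3600
  day_end <- twilight$dusk[hit] - 3600
  qpos$date <- date
  qpos$diel <- ifelse(mid >= day_start & mid <= day_end, "day", "night")
  qpos
}

#' Daily horizontal 95% kernel utilization distribution (dH-KUD)
#'
#' Fits a bivariate Gaussian kernel density (bandwidth `h`) to one fish-day
#' of q-position coordinates, evaluated on a `cell` x `cell` m in-lake grid.
#' Density outside the shoreline is discarded and the remaining mass
#' renormalized to one; the returned area (ha) is that of the smallest set
#' of highest-density cells holding at least `level` of the mass. The value
#' is only defined for days with more than `min_day` daytime *and* more than
#' `min_night` night-time q-positions (`NA` otherwise). A day whose
#' positions are all identical returns the single-cell area (0.01 ha for
#' 10-m cells) by convention.
#'
#' @param qpos One tag-day of q-positions with columns `x`, `y` and `diel`
#'   (from [split_diel()]).
#' @param lake A `lake_grid`.
#' @param h Kernel bandwidth (m).
#' @param cell Grid cell size (m).
#' @param level Utilization level.
#' @param min_day,min_night Strict minimum daytime/night-time q-position
#'   counts.
#' @return Area in hectares, or `NA`.
#' @export
daily_hkud <- function(qpos, lake, h = 50, cell = 10, level = 0.95,
                       min_day = 12, min_night = 12) {
  if (!"diel" %in% names(qpos))
    stop("q-positions must carry a `diel` label; see split_diel()",
         call. = FALSE)
  if (!(sum(qpos$diel == "day") > min_day &&
        sum(qpos$diel == "night") > min_night)) return(NA_real_)
  px <- qpos$x[!is.na(qpos$x)]
  py <- qpos$y[!is.na(qpos$x)]
  if (length(px) == 0) return(NA_real_)
  if (length(unique(px)) == 1 && length(unique(py)) == 1)
    return(cell^2 / 1e4)
  # the Gaussian kernel separates in x and y, so the density on the
  # rectangular cell grid is a matrix product of per-axis kernel factors;
  # mass beyond 5 bandwidths of every point (< 1e-6) is neglected
  half <- floor(lake$radius / cell)
  xs <- seq(max(-half, floor((min(px) - 5 * h) / cell)),
            min(half, ceiling((max(px) + 5 * h) / cell))) * cell
  ys <- seq(max(-half, floor((min(py) - 5 * h) / cell)),
            min(half, ceiling((max(py) + 5 * h) / cell))) * cell
  ex <- exp(-outer(xs, px, "-")^2 / (2 * h^2))
  ey <- exp(-outer(ys, py, "-")^2 / (2 * h^2))
  dens <- ex %*% t(ey)
  in_lake_cell <- outer(xs^2, ys^2, "+") < lake$radius^2
  p <- dens[in_lake_cell]
  p <- sort(p / sum(p), decreasing = TRUE)
  n <- which(cumsum(p) >= level)[1]
  n * cell^2 / 1e4
}

#' Daily vertical kernel spread (dV-KS)
#'
#' One-dimensional Gaussian kernel density with fixed bandwidth `bw` fitted
#' to a day's utilized depths; returns the total length (m) of the smallest
#' highest-density set of depth-grid points holding at least `level` of the
#' mass. With a single distinct depth this approaches the closed-form 95%
#' width of one Gaussian kernel, `2 * 1.96 * bw` (about 1.57 m at the
#' default).
#'
#' @param depths Numeric depths (m); at least two non-missing values.
#' @param bw Kernel bandwidth (m).
#' @param level Mass level.
#' @param grid_step Depth-grid resolution (m).
#' @return Length in metres, or `NA` with fewer than two depths.
#' @export
daily_vks <- function(depths, bw = 0.4, level = 0.95, grid_step = 0.05) {
  depths <- depths[!is.na(depths)]
  if (length(depths) < 2) return(NA_real_)
  grid <- seq(min(depths) - 4 * bw, max(depths) + 4 * bw, by = grid_step)
  dens <- rowMeans(outer(grid, depths, function(g, d) dnorm(g, d, bw)))
  p <- dens / sum(dens)
  p <- sort(p, decreasing = TRUE)
  n <- which(cumsum(p) >= level)[1]
  n * grid_step
}

#' Daily swimming activity between consecutive q-positions
#'
#' Horizontal activity is the planar distance between q-positions in
#' *adjacent* 15-min intervals divided by 900 s, expressed in body lengths
#' per second; vertical activity is the absolute depth change per second
#' (m/s). Pairs spanning non-adjacent intervals are excluded; the daily
#' value is the mean over pairs.
#'
#' @param qpos One tag-day of q-positions, sorted by `interval_start`.
#' @param body_length Body length (cm).
#' @return A named list: `horiz` (BL/s), `vert` (m/s); `NA` where no
#'   adjacent pair exists.
#' @export
daily_activity <- function(qpos, body_length) {
  if (body_length <= 0) stop("`body_length` must be positive", call. = FALSE)
  q <- qpos[order(qpos$interval_start), , drop = FALSE]
  if (nrow(q) < 2) return(list(horiz = NA_real_, vert = NA_real_))
  adj <- diff(as.numeric(q$interval_start)) == Q_INTERVAL
  dx <- diff(q$x); dy <- diff(q$y); dz <- abs(diff(q$depth))
  hs <- (sqrt(dx^2 + dy^2) / Q_INTERVAL / (body_length / 100))[adj]
  vs <- (dz / Q_INTERVAL)[adj]
  list(horiz = if (any(!is.na(hs))) mean(hs, na.rm = TRUE) else NA_real_,
       vert = if (any(!is.na(vs))) mean(vs, na.rm = TRUE) else NA_real_)
}

#' Daily time in open water (TOW)
#'
#' The fraction of a day's q-positions lying at least 5 m above the lake
#' bottom. A distance of exactly 5 m counts as open water. Also reports
#' whether the day was all-benthic (TOW = 0) or all-pelagic (TOW = 1).
#'
#' @param dist_to_bottom Numeric distances to bottom (m).
#' @param threshold Open-water threshold (m), inclusive.
#' @return A named list: `tow` in `[0, 1]` (or `NA` if no distance is
#'   defined), `all_benthic`, `all_pelagic`.
#' @export
daily_tow <- function(dist_to_bottom, threshold = 5) {
  d <- dist_to_bottom[!is.na(dist_to_bottom)]
  if (length(d) == 0)
    return(list(tow = NA_real_, all_benthic = NA, all_pelagic = NA))
  tow <- mean(d >= threshold)
  list(tow = tow, all_benthic = tow == 0, all_pelagic = tow == 1)
}

#' Daily mean depth
#'
#' @param depths Numeric q-position depths (m) for one tag-day.
#' @return Arithmetic mean (m), `NA` if none.
#' @export
daily_mean_depth <- function(depths) {
  if (all(is.na(depths))) NA_real_ else mean(depths, na.rm = TRUE)
}

#' Daily surface-layer water temperature
#'
#' Mean over all logger readings at depths of at most `max_depth` m, per
#' date.
#'
#' @param readings A logger tibble (`logger_id`, `timestamp`, `depth`,
#'   `temp`), e.g. from [make_temperature()].
#' @param max_depth Deepest logger depth included (m).
#' @return A tibble: `date`, `temp` (degrees C).
#' @export
daily_temperature <- function(readings, max_depth = 3) {
  readings |>
    dplyr::filter(.data$depth <= max_depth) |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(temp = mean(.data$temp), .groups = "drop")
}

#' Day length from a twilight table
#'
#' @param twilight A twilight tibble (`date`, `dawn`, `dusk`).
#' @return `twilight` with a `day_length` column in hours.
#' @export
day_length <- function(twilight) {
  twilight$day_length <-
    as.numeric(twilight$dusk - twilight$dawn, units = "hours")
  twilight
}

#' Compute all daily behavioural traits per individual
#'
#' Convenience wrapper running [split_diel()], [daily_hkud()],
#' [daily_vks()], [daily_activity()], [daily_tow()] and
#' [daily_mean_depth()] for every tag and date.
#'
#' @param qpos A q-position tibble with `dist_to_bottom` (see
#'   [distance_to_bottom()]).
#' @param lake A `lake_grid`.
#' @param twilight A twilight table covering all dates.
#' @param body_length Named numeric vector of body lengths (cm) by
#'   `tag_id`, or a single value recycled to all tags.
#' @param ... Passed to [daily_hkud()] (e.g. `h`, `cell`).
#' @return A tibble with one row per tag x date: `tag_id`, `date`,
#'   `dH_KUD` (ha), `dV_KS` (m), `mean_depth` (m), `horiz_activity` (BL/s),
#'   `vert_activity` (m/s), `TOW`, `n_day_q`, `n_night_q`.
#' @export
daily_traits <- function(qpos, lake, twilight, body_length, ...) {
  qpos <- split_diel(qpos, twilight)
  if (is.null(names(body_length))) {
    bl <- setNames(rep_len(body_length, length(unique(qpos$tag_id))),
                   unique(qpos$tag_id))
  } else bl <- body_length
  qdf <- as.data.frame(qpos)    # plain-frame subsetting in the group loop
  groups <- split(seq_len(nrow(qdf)),
                  list(qpos$tag_id, qpos$date), drop = TRUE)
  has_d2b <- "dist_to_bottom" %in% names(qdf)
  rows <- lapply(groups, function(i) {
    q <- qdf[i, , drop = FALSE]
    act <- daily_activity(q, bl[[q$tag_id[1]]])
    tow <- daily_tow(if (has_d2b) q$dist_to_bottom else NA_real_)
    list(tag_id = q$tag_id[1], date = q$date[1],
         dH_KUD = daily_hkud(q, lake, ...),
         dV_KS = daily_vks(q$depth),
         mean_depth = daily_mean_depth(q$depth),
         horiz_activity = act$horiz, vert_activity = act$vert,
         TOW = tow$tow,
         n_day_q = sum(q$diel == "day"), n_night_q = sum(q$diel == "night"))
  })
  col <- function(nm) unname(vapply(rows, `[[`, numeric(1), nm))
  tibble::tibble(
    tag_id = vapply(rows, `[[`, character(1), "tag_id"),
    date = as.Date(vapply(rows, function(r) as.character(r$date),
                          character(1))),
    dH_KUD = col("dH_KUD"), dV_KS = col("dV_KS"),
    mean_depth = col("mean_depth"),
    horiz_activity = col("horiz_activity"),
    vert_activity = col("vert_activity"), TOW = col("TOW"),
    n_day_q = as.integer(col("n_day_q")),
    n_night_q = as.integer(col("n_night_q"))) |>
    dplyr::arrange(.data$tag_id, .data$date)
}
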