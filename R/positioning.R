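#' Quality-filter raw position estimates
#'
#' Applies three standard telemetry cleaning rules, in order: (1) exact
#' duplicates (same tag, same timestamp) are collapsed to one row; (2) fixes
#' falling outside the shoreline polygon buffered outward by
#' `boundary_buffer` are removed; (3) fixes implying a sustained speed above
#' `max_speed` to *both* temporal neighbours are removed, iterating until no
#' further removals (endpoint fixes, which have a single neighbour, are
#' retained). Depth-only rows (no coordinates) are only subject to the
#' duplicate rule. The function is idempotent.
#'
#' @param fixes A tibble of position estimates with columns `tag_id`,
#'   `timestamp`, `x`, `y`, `depth` (and optionally `has_xy`).
#' @param lake A `lake_grid`, or `NULL` to skip the boundary rule (with a
#'   warning).
#' @param max_speed Speed threshold (m/s).
#' @param boundary_buffer Outward shoreline buffer (m).
#' @return The filtered tibble, sorted by tag and time, with an attribute
#'   `removal_counts` logging removals per rule.
#' @export
filter_positions <- function(fixes, lake = NULL, max_speed = 2,
                             boundary_buffer = 50) {
  if (nrow(fixes) == 0) return(fixes)
  if (!"has_xy" %in% names(fixes)) fixes$has_xy <- !is.na(fixes$x)
  fixes <- dplyr::arrange(fixes, .data$tag_id, .data$timestamp)
  n0 <- nrow(fixes)
  tag_i <- match(fixes$tag_id, unique(fixes$tag_id))
  dup <- duplicated(tag_i * 2^40 + as.numeric(fixes$timestamp))
  fixes <- fixes[!dup, , drop = FALSE]
  n_dup <- n0 - nrow(fixes)

  n_bound <- 0L
  if (is.null(lake)) {
    warning("no lake supplied; boundary rule skipped", call. = FALSE)
  } else {
    out <- fixes$has_xy & !in_lake(lake, fixes$x, fixes$y, boundary_buffer)
    n_bound <- sum(out)
    fixes <- fixes[!out, , drop = FALSE]
  }

  n_speed <- 0L
  split_tags <- split(seq_len(nrow(fixes)), fixes$tag_id)
  drop_all <- logical(nrow(fixes))
  for (idx in split_tags) {
    xy <- idx[fixes$has_xy[idx]]
    repeat {
      if (length(xy) < 3) break
      t <- as.numeric(fixes$timestamp[xy])
      dx <- diff(fixes$x[xy]); dy <- diff(fixes$y[xy]); dt <- diff(t)
      sp <- sqrt(dx^2 + dy^2) / pmax(dt, .Machine$double.eps)
      k <- length(xy)
      bad <- c(FALSE, sp[-(k - 1)] > max_speed & sp[-1] > max_speed, FALSE)
      if (!any(bad)) break
      drop_all[xy[bad]] <- TRUE
      n_speed <- n_speed + sum(bad)
      xy <- xy[!bad]
    }
  }
  fixes <- fixes[!drop_all, , drop = FALSE]
  attr(fixes, "removal_counts") <-
    c(duplicate = n_dup, boundary = n_bound, speed = n_speed)
  fixes
}

# floor a POSIXct onto the 900-s UTC grid
q_floor <- function(t) {
  as.POSIXct(floor(as.numeric(t) / Q_INTERVAL) * Q_INTERVAL,
             origin = "1970-01-01", tz = "UTC")
}

#' Regularize position estimates into 15-minute q-positions
#'
#' Averages all fixes of each tag within each clock-aligned 15-min interval:
#' planar coordinates are the mean over positionable fixes, depth is the mean
#' over all fixes carrying a depth reading (computed even when no coordinates
#' exist in the interval). Intervals with neither are absent, so at most 96
#' q-positions exist per tag per day.
#'
#' @param fixes A filtered tibble from [filter_positions()].
#' @return A tibble of q-positions: `tag_id`, `interval_start` (POSIXct on
#'   the 900-s grid), `x`, `y`, `depth`, `n_fixes` (positionable fixes),
#'   `n_depth_fixes`, `interpolated` (all `FALSE` here).
#' @export
regularize <- function(fixes) {
  if (!"has_xy" %in% names(fixes)) fixes$has_xy <- !is.na(fixes$x)
  fixes <- dplyr::arrange(fixes, .data$tag_id, .data$timestamp)
  iv <- q_floor(fixes$timestamp)
  n <- nrow(fixes)
  tag_i <- match(fixes$tag_id, unique(fixes$tag_id))
  key <- tag_i * 2^40 + as.numeric(iv)
  first <- c(TRUE, key[-1] != key[-n])       # groups are contiguous runs
  gid <- cumsum(first)
  zero <- function(v) ifelse(is.na(v), 0, v)
  has_d <- !is.na(fixes$depth)
  sums <- rowsum(
    cbind(x = zero(fixes$x) * fixes$has_xy,
          y = zero(fixes$y) * fixes$has_xy,
          depth = zero(fixes$depth),
          n_xy = as.numeric(fixes$has_xy),
          n_d = as.numeric(has_d)),
    gid, reorder = FALSE)
  n_xy <- unname(sums[, "n_xy"])
  n_d <- unname(sums[, "n_d"])
  sums <- unname(sums)
  colnames(sums) <- c("x", "y", "depth", "n_xy", "n_d")
  out <- tibble::tibble(
    tag_id = fixes$tag_id[first],
    interval_start = iv[first],
    x = ifelse(n_xy > 0, sums[, "x"] / n_xy, NA_real_),
    y = ifelse(n_xy > 0, sums[, "y"] / n_xy, NA_real_),
    depth = ifelse(n_d > 0, sums[, "depth"] / n_d, NA_real_),
    n_fixes = as.integer(n_xy),
    n_depth_fixes = as.integer(n_d),
    interpolated = FALSE)
  out[out$n_fixes > 0 | out$n_depth_fixes > 0, , drop = FALSE]
}

#' Interpolate short, local gaps in q-position series
#'
#' For each run of missing 15-min intervals bounded by q-positions P (last
#' before) and Q (first after), the gap is filled by linear interpolation in
#' x, y and depth if and only if all three conditions hold strictly:
#' (a) the time between P and Q is shorter than `max_gap`, (b) their planar
#' distance is less than `max_dist`, and (c) their depth difference is less
#' than `max_ddepth`. Runs whose bounding q-positions lack coordinates or
#' depth are left unfilled (the conditions are unevaluable). Filled records
#' are flagged `interpolated` and carry `n_fixes = 0`. Idempotent.
#'
#' @param qpos A q-position tibble from [regularize()].
#' @param max_gap Maximum P-to-Q time difference (s), exclusive.
#' @param max_dist Maximum P-to-Q planar distance (m), exclusive.
#' @param max_ddepth Maximum P-to-Q depth difference (m), exclusive.
#' @return The q-position tibble with interpolated rows inserted, sorted.
#' @export
interpolate_gaps <- function(qpos, max_gap = 7200, max_dist = 100,
                             max_ddepth = 2) {
  q <- qpos[order(qpos$tag_id, qpos$interval_start), , drop = FALSE]
  n <- nrow(q)
  if (n < 2) return(q)
  t <- as.numeric(q$interval_start)
  same_tag <- q$tag_id[-n] == q$tag_id[-1]
  dt <- t[-1] - t[-n]
  n_missing <- dt / Q_INTERVAL - 1
  dx <- q$x[-1] - q$x[-n]
  dy <- q$y[-1] - q$y[-n]
  dz <- q$depth[-1] - q$depth[-n]
  fillable <- same_tag & n_missing >= 1 &
    !is.na(dx) & !is.na(dz) &
    dt < max_gap & sqrt(dx^2 + dy^2) < max_dist & abs(dz) < max_ddepth
  idx <- which(fillable)
  if (length(idx) == 0) return(q)
  reps <- n_missing[idx]
  i <- rep(idx, reps)                                   # index of P per fill
  step <- sequence(reps)                                # 1..n_missing per gap
  frac <- step / (n_missing[i] + 1)
  fill <- tibble::tibble(
    tag_id = q$tag_id[i],
    interval_start = q$interval_start[i] + Q_INTERVAL * step,
    x = q$x[i] + frac * dx[i],
    y = q$y[i] + frac * dy[i],
    depth = q$depth[i] + frac * dz[i],
    n_fixes = 0L, n_depth_fixes = 0L, interpolated = TRUE)
  extra <- setdiff(names(q), names(fill))
  for (col in extra) fill[[col]] <- q[[col]][NA_integer_][rep(1, nrow(fill))]
  dplyr::bind_rows(q, fill[names(q)]) |>
    dplyr::arrange(.data$tag_id, .data$interval_start)
}

#' Distance to bottom for q-positions
#'
#' Sets `dist_to_bottom = bottom_depth(x, y) - depth`. When the raw fixes
#' are supplied, intervals with positionable fixes instead use the mean of
#' the per-fix distances (each fix's local bottom depth minus its own sensor
#' depth), which matters wherever the bottom varies within an interval.
#' Positions beyond the shoreline keep their record but get `NA` distance,
#' with a warning.
#'
#' @param qpos A q-position tibble.
#' @param lake A `lake_grid`.
#' @param fixes Optionally, the filtered raw fixes the q-positions were
#'   built from.
#' @return `qpos` with a `dist_to_bottom` column (m).
#' @export
distance_to_bottom <- function(qpos, lake, fixes = NULL) {
  qpos$dist_to_bottom <- NA_real_
  ok <- !is.na(qpos$x) & !is.na(qpos$depth)
  bd <- bottom_depth(lake, qpos$x[ok], qpos$y[ok])
  qpos$dist_to_bottom[ok] <- bd - qpos$depth[ok]
  if (!is.null(fixes) && nrow(fixes) > 0) {
    if (!"has_xy" %in% names(fixes)) fixes$has_xy <- !is.na(fixes$x)
    f <- fixes[fixes$has_xy & !is.na(fixes$depth), , drop = FALSE]
    if (nrow(f) > 0) {
      f$interval_start <- q_floor(f$timestamp)
      f$d2b <- bottom_depth(lake, f$x, f$y) - f$depth
      tags <- unique(c(f$tag_id, qpos$tag_id))
      key_f <- match(f$tag_id, tags) * 2^40 + as.numeric(f$interval_start)
      sums <- rowsum(cbind(d2b = f$d2b, n = 1), key_f, reorder = FALSE)
      key_q <- match(qpos$tag_id, tags) * 2^40 +
        as.numeric(qpos$interval_start)
      per <- list(d2b = unname(sums[, "d2b"] / sums[, "n"]))
      hit <- match(key_q, unique(key_f))
      use <- !is.na(hit) & !qpos$interpolated & qpos$n_fixes > 0
      qpos$dist_to_bottom[use] <- per$d2b[hit[use]]
    }
  }
  if (anyNA(qpos$dist_to_bottom[ok]))
    warning("some q-positions lie beyond the shoreline; distance to bottom ",
            "left NA", call. = FALSE)
  qpos
}

# suffix standard deviation of v ignoring NAs: sd of v[i..n] for each i
suffix_sd <- function(v) {
  ok <- !is.na(v)
  vv <- ifelse(ok, v, 0)
  n <- length(v)
  m <- rev(cumsum(rev(ok)))
  s1 <- rev(cumsum(rev(vv)))
  s2 <- rev(cumsum(rev(vv^2)))
  out <- rep(NA_real_, n)
  good <- m >= 2
  out[good] <- sqrt(pmax(0, (s2[good] - s1[good]^2 / m[good]) / (m[good] - 1)))
  out
}

#' Flag dead or tag-expelling individuals
#'
#' A tag is flagged when, from some time onward until the end of its series,
#' both the horizontal position and the depth stay essentially constant:
#' the standard deviations of x, y and depth over the whole remaining suffix
#' fall below the thresholds, and the suffix spans at least `window`
#' seconds. A temporarily stationary fish that moves again later is not
#' flagged, because the criterion applies to the suffix only. Flagged tags
#' should be truncated at the reported onset before trait computation.
#'
#' @param qpos A q-position tibble.
#' @param window Minimum stationary-suffix duration (s).
#' @param xy_sd_max Maximum positional SD (m).
#' @param depth_sd_max Maximum depth SD (m).
#' @return A tibble: `tag_id`, `flagged`, `truncation_time` (POSIXct or NA).
#' @export
flag_mortality <- function(qpos, window = 48 * 3600, xy_sd_max = 5,
                           depth_sd_max = 0.3) {
  res <- lapply(split(qpos, qpos$tag_id), function(q) {
    q <- q[order(q$interval_start), , drop = FALSE]
    t <- as.numeric(q$interval_start)
    span_ok <- (t[length(t)] - t) >= window
    still <- suffix_sd(q$x) < xy_sd_max & suffix_sd(q$y) < xy_sd_max &
      suffix_sd(q$depth) < depth_sd_max
    hit <- which(span_ok & !is.na(still) & still)
    tibble::tibble(
      tag_id = q$tag_id[1],
      flagged = length(hit) > 0,
      truncation_time = if (length(hit)) q$interval_start[min(hit)]
                        else as.POSIXct(NA, tz = "UTC"))
  })
  dplyr::bind_rows(res)
}
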