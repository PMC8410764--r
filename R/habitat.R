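#' Discretize macrophyte height and coverage
#'
#' Height is binned into 100 bins of 2 cm (0-200 cm; taller vegetation
#' saturates at bin 100) and coverage into 100 bins of 1%. Exact zeros map
#' to bin 0, so any non-zero presence scores at least 1 on each axis.
#'
#' @param height Height (cm), vectorized.
#' @param coverage Coverage (percent), vectorized.
#' @return A list with integer vectors `h_bin` and `c_bin`, each in 0-100.
#' @export
discretize_structure <- function(height, coverage) {
  if (any(height < 0) || any(coverage < 0) || any(coverage > 100))
    stop("height must be >= 0 and coverage within [0, 100]", call. = FALSE)
  list(h_bin = as.integer(pmin(ceiling(height / 2), 100)),
       c_bin = as.integer(pmin(ceiling(coverage), 100)))
}

# collapse a quadrat's species rows to one total coverage and a
# coverage-weighted mean height (midpoint of recorded min/max per species)
aggregate_quadrat <- function(coverage, height_min, height_max) {
  ok <- !is.na(coverage) & coverage > 0
  if (!any(ok)) return(list(coverage = 0, height = 0))
  h_mid <- (height_min[ok] + height_max[ok]) / 2
  list(coverage = min(sum(coverage[ok]), 100),
       height = sum(coverage[ok] * h_mid) / sum(coverage[ok]))
}

#' Structural Complexity Index of macrophyte quadrats
#'
#' SCI is the product of discretized macrophyte height (100 bins of 2 cm)
#' and discretized coverage (100 bins of 1%), ranging from 0 (no
#' macrophytes) to 10,000 (100% coverage of vegetation at least 2 m tall).
#' Multi-species quadrats are first collapsed to total coverage (capped at
#' 100%) and a coverage-weighted mean height.
#'
#' @param quadrats A transect-quadrat tibble (see
#'   [make_macrophyte_survey()]): columns `lake`, `period`, `transect_id`,
#'   `depth_bin`, `species`, `coverage`, `height_min`, `height_max`.
#' @return A tibble with one row per quadrat (`lake`, `period`,
#'   `transect_id`, `depth_bin`) and its integer `sci`.
#' @export
sci <- function(quadrats) {
  quadrats |>
    dplyr::group_by(.data$lake, .data$period, .data$transect_id,
                    .data$depth_bin) |>
    dplyr::summarise(
      sci = {
        agg <- aggregate_quadrat(.data$coverage, .data$height_min,
                                 .data$height_max)
        b <- discretize_structure(agg$height, agg$coverage)
        as.integer(b$h_bin * b$c_bin)
      },
      .groups = "drop")
}

#' Mean SCI depth profile by stratum
#'
#' @param quadrats A transect-quadrat tibble.
#' @param by Grouping columns for the strata.
#' @return A tibble of stratum means (`mean_sci`) with quadrat counts.
#' @export
sci_profile <- function(quadrats, by = c("lake", "period", "depth_bin")) {
  sci(quadrats) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(mean_sci = mean(.data$sci), n = dplyr::n(),
                     .groups = "drop")
}

#' Permutation test for a mean SCI difference between two lakes
#'
#' Two-sided permutation inference on the difference of group means,
#' permuting lake labels over quadrats. The Monte-Carlo p-value uses the
#' add-one correction `(1 + #extreme) / (1 + n_perm)`; with
#' `exhaustive = TRUE` all label assignments are enumerated and the exact
#' proportion `#extreme / #assignments` is returned.
#'
#' @param sci_a,sci_b Per-quadrat SCI values for the two lakes.
#' @param n_perm Number of random permutations (>= 99).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all assignments instead of sampling (only
#'   sensible for small groups).
#' @return A list: `statistic` (observed mean difference), `p`, `n_perm`.
#' @export
sci_lake_test <- function(sci_a, sci_b, n_perm = 9999, seed = 1L,
                          exhaustive = FALSE) {
  if (length(sci_a) == 0 || length(sci_b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  obs <- mean(sci_a) - mean(sci_b)
  pool <- c(sci_a, sci_b)
  na <- length(sci_a)
  if (exhaustive) {
    sets <- utils::combn(length(pool), na)
    d <- apply(sets, 2, function(i) mean(pool[i]) - mean(pool[-i]))
    p <- mean(abs(d) >= abs(obs) - 1e-12)
    return(list(statistic = obs, p = p, n_perm = ncol(sets)))
  }
  if (n_perm < 99) stop("`n_perm` must be >= 99", call. = FALSE)
  set.seed(seed)
  d <- replicate(n_perm, {
    i <- sample.int(length(pool), na)
    mean(pool[i]) - mean(pool[-i])
  })
  list(statistic = obs,
       p = (1 + sum(abs(d) >= abs(obs) - 1e-12)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Permutation test for a lake-by-period interaction in SCI
#'
#' The statistic is the difference-in-differences of stratum means,
#' `(Sept - June) in lake A minus (Sept - June) in lake B`; the null
#' distribution is built by permuting period labels within each lake.
#'
#' @param quadrat_sci A tibble with columns `lake`, `period`, `sci` (one
#'   row per quadrat, e.g. from [sci()]).
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return A list: `statistic`, `p`, `n_perm`.
#' @export
sci_interaction_test <- function(quadrat_sci, n_perm = 9999, seed = 1L) {
  if (n_perm < 99) stop("`n_perm` must be >= 99", call. = FALSE)
  lakes <- sort(unique(quadrat_sci$lake))
  periods <- sort(unique(quadrat_sci$period))
  if (length(lakes) != 2 || length(periods) != 2)
    stop("need exactly two lakes and two periods", call. = FALSE)
  did <- function(d) {
    m <- tapply(d$sci, list(d$lake, d$period), mean)
    (m[lakes[1], periods[2]] - m[lakes[1], periods[1]]) -
      (m[lakes[2], periods[2]] - m[lakes[2], periods[1]])
  }
  obs <- did(quadrat_sci)
  set.seed(seed)
  idx_by_lake <- split(seq_len(nrow(quadrat_sci)), quadrat_sci$lake)
  d <- replicate(n_perm, {
    perm <- quadrat_sci
    for (i in idx_by_lake) perm$period[i] <- sample(perm$period[i])
    did(perm)
  })
  list(statistic = obs,
       p = (1 + sum(abs(d) >= abs(obs) - 1e-12)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Gillnet catch per unit effort
#'
#' Standardizes gillnet catches to numbers (NPUE) and biomass (BPUE) of fish
#' per 1000 m^2 of net per night.
#'
#' @param catch A tibble with columns `net_area` (m^2), `nights`, `n_fish`
#'   and `biomass` (kg); other columns (lake, habitat, depth layer) pass
#'   through.
#' @return `catch` with `NPUE` and `BPUE` columns appended.
#' @export
cpue <- function(catch) {
  if (any(catch$net_area <= 0)) stop("`net_area` must be > 0", call. = FALSE)
  if (any(catch$nights < 1)) stop("`nights` must be >= 1", call. = FALSE)
  catch$NPUE <- catch$n_fish * 1000 / (catch$net_area * catch$nights)
  catch$BPUE <- catch$biomass * 1000 / (catch$net_area * catch$nights)
  catch
}
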