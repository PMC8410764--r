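#' Littoral reliance from a two-source delta-13-C mixing model
#'
#' Under the standard two-end-member mixing model, the fraction of a
#' consumer's carbon derived from littoral sources is
#' `LR = (consumer - pelagic) / (littoral - pelagic)`. Values outside
#' `[0, 1]` (a consumer isotopically beyond an end-member) are returned
#' unclipped with `out_of_range = TRUE`, leaving exclusion to the analyst.
#' An optional per-trophic-level fractionation offset is subtracted from the
#' consumer value first (default 0: scale delta-13-C is compared directly to
#' the end-members).
#'
#' @param consumer_d13C Consumer delta-13-C (per mil), vectorized.
#' @param littoral_d13C,pelagic_d13C End-member delta-13-C values (per mil).
#' @param eps Minimum end-member separation (per mil); closer end-members
#'   make the model unidentifiable and raise an error.
#' @param fractionation Trophic fractionation offset (per mil) subtracted
#'   from the consumer value.
#' @return A tibble: `LR`, `out_of_range`.
#' @export
littoral_reliance <- function(consumer_d13C, littoral_d13C, pelagic_d13C,
                              eps = 0.5, fractionation = 0) {
  if (abs(littoral_d13C - pelagic_d13C) <= eps)
    stop("littoral and pelagic end-members are closer than `eps`; ",
         "the mixing model is unidentifiable", call. = FALSE)
  lr <- (consumer_d13C - fractionation - pelagic_d13C) /
    (littoral_d13C - pelagic_d13C)
  tibble::tibble(LR = lr, out_of_range = lr < 0 | lr > 1)
}

#' Fraser-Lee back-calculation of length-at-age
#'
#' `L_i = c + (L_c - c) * S_i / S_c`: length at annulus i from the annulus
#' radius, the radius and body length at capture, and the biological
#' intercept `c` (body length at scale formation). `c` is a population
#' constant the caller must supply.
#'
#' @param S_i Scale radii at each annulus (any consistent units).
#' @param S_c Scale radius at capture.
#' @param L_c Body length at capture (cm).
#' @param c Biological intercept (cm); must satisfy `c < L_c`.
#' @return Numeric lengths-at-age (cm).
#' @export
fraser_lee <- function(S_i, S_c, L_c, c) {
  if (any(S_c <= 0)) stop("`S_c` must be positive", call. = FALSE)
  if (any(c >= L_c)) stop("intercept `c` must be below the capture length",
                          call. = FALSE)
  c + (L_c - c) * S_i / S_c
}

#' Average back-calculated lengths over a fish's scales
#'
#' Back-calculates length-at-age with [fraser_lee()] separately for each
#' scale and averages per annulus (averaging after back-calculation;
#' set `average = "radii"` to average annulus radii first instead).
#'
#' @param scales A scale-reading tibble for one fish (see [make_scales()]):
#'   columns `fish_id`, `scale_id`, `age`, `S_i`, `S_c`, `L_c`, `c`.
#' @param average `"lengths"` (default) or `"radii"`.
#' @return A tibble: `fish_id`, `age`, `length` (cm).
#' @export
average_scales <- function(scales, average = c("lengths", "radii")) {
  average <- match.arg(average)
  stopifnot(length(unique(scales$fish_id)) == 1)
  counts <- table(scales$scale_id)
  if (length(unique(counts)) > 1)
    stop("scales disagree on annulus count: ",
         paste(names(counts), counts, sep = "=", collapse = ", "),
         call. = FALSE)
  if (average == "radii") {
    by_age <- scales |>
      dplyr::group_by(.data$fish_id, .data$age) |>
      dplyr::summarise(S_i = mean(.data$S_i), S_c = mean(.data$S_c),
                       L_c = .data$L_c[1], c = .data$c[1], .groups = "drop")
    by_age$length <- fraser_lee(by_age$S_i, by_age$S_c, by_age$L_c,
                                by_age$c)
    return(by_age[c("fish_id", "age", "length")])
  }
  scales$length <- fraser_lee(scales$S_i, scales$S_c, scales$L_c, scales$c)
  scales |>
    dplyr::group_by(.data$fish_id, .data$age) |>
    dplyr::summarise(length = mean(.data$length), .groups = "drop")
}

#' Growth increment in the year prior to tagging
#'
#' The difference between the last two back-calculated lengths-at-age (or
#' at an explicit annulus index): the body increment most relevant to
#' behaviour during the study year.
#'
#' @param lengths_at_age Increasing numeric lengths (cm).
#' @param year_index Annulus index of the year prior to tagging; defaults to
#'   the last annulus.
#' @return Increment (cm).
#' @export
last_increment <- function(lengths_at_age, year_index = length(lengths_at_age)) {
  if (length(lengths_at_age) < 2 || year_index < 2)
    stop("need at least two annuli to form an increment", call. = FALSE)
  lengths_at_age[year_index] - lengths_at_age[year_index - 1]
}
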