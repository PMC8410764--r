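#' Simulate a consumer stable-isotope sample
#'
#' Draws the consumer's scale delta-13-C as the two-end-member mixture
#' `LR * littoral + (1 - LR) * pelagic` plus Gaussian noise, so that
#' [littoral_reliance()] is its exact inverse at zero noise.
#'
#' @param fish A [fish_spec()] (supplies `true_LR`).
#' @param end_members Numeric `c(littoral, pelagic)` delta-13-C values
#'   (per mil); must be distinct.
#' @param noise_sd Analytical + ecological noise SD (per mil).
#' @param seed Integer seed.
#' @return A one-row tibble: `sample_id`, `d13C`, `d15N`, `role`.
#' @export
make_isotopes <- function(fish, end_members = c(-20, -30), noise_sd = 0.5,
                          seed = 1L) {
  stopifnot(inherits(fish, "fish_spec"), length(end_members) == 2)
  if (end_members[1] == end_members[2])
    stop("littoral and pelagic end-members must be distinct", call. = FALSE)
  set.seed(seed)
  d13c <- fish$true_LR * end_members[1] +
    (1 - fish$true_LR) * end_members[2] + rnorm(1, 0, noise_sd)
  tibble::tibble(sample_id = fish$tag_id, d13C = d13c,
                 d15N = 12 + rnorm(1, 0, noise_sd), role = "consumer")
}

#' Simulate scale readings for back-calculation
#'
#' Produces `n_scales` scale readings whose annulus radii follow the
#' Fraser-Lee proportionality `S_i / S_c = (L_i - c) / (L_c - c)` for the
#' fish's true lengths-at-age, each radius multiplied by lognormal reading
#' noise (mean 1). At zero noise, [fraser_lee()] recovers the true lengths
#' exactly.
#'
#' @param fish A [fish_spec()] with `true_lengths_at_age` set; the last
#'   entry is the length at capture.
#' @param c Biological intercept (cm), the body length at scale formation;
#'   must be below the first length-at-age.
#' @param n_scales Number of scales read per fish.
#' @param noise_sd SD of the lognormal radius noise (on the log scale).
#' @param S_c True scale radius at capture (arbitrary units).
#' @param seed Integer seed.
#' @return A tibble with one row per scale and annulus: `fish_id`,
#'   `scale_id`, `age`, `S_i`, `S_c`, `L_c`, `c`.
#' @export
make_scales <- function(fish, c = 3.5, n_scales = 3, noise_sd = 0.02,
                        S_c = 10, seed = 1L) {
  stopifnot(inherits(fish, "fish_spec"))
  L <- fish$true_lengths_at_age
  if (is.null(L)) stop("fish has no `true_lengths_at_age`", call. = FALSE)
  if (c >= L[1]) stop("intercept `c` must be below the first length-at-age",
                      call. = FALSE)
  L_c <- L[length(L)]
  set.seed(seed)
  out <- lapply(seq_len(n_scales), function(s) {
    S_i <- S_c * (L - c) / (L_c - c)
    if (noise_sd > 0) S_i <- S_i * exp(rnorm(length(L), 0, noise_sd))
    tibble::tibble(fish_id = fish$tag_id,
                   scale_id = paste0(fish$tag_id, "_s", s),
                   age = seq_along(L), S_i = S_i, S_c = S_c,
                   L_c = L_c, c = c)
  })
  dplyr::bind_rows(out)
}
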