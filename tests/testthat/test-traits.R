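lk <- tiny_lake()
tw <- flat_twilight("2015-06-01")        # civil dawn 05:00, dusk 21:00 UTC

test_that("diel labels switch one hour inside civil twilight", {
  at <- function(hhmm) {
    qp(t = paste("2015-06-01", hhmm))
  }
  lab <- function(hhmm) split_diel(at(hhmm), tw)$diel
  expect_equal(lab("06:30:00"), "day")     # after dawn + 1 h (06:00)
  expect_equal(lab("05:30:00"), "night")   # before 06:00
  expect_equal(lab("19:30:00"), "day")     # before dusk - 1 h (20:00)
  expect_equal(lab("20:30:00"), "night")
  expect_error(split_diel(qp(t = "2015-07-04 10:00:00"), tw), "2015-07-04")
})

test_that("dH-KUD needs more than 12 day and 12 night q-positions", {
  pts <- kud_day(rnorm(24, 0, 30), rnorm(24, 0, 30))  # 12 day / 12 night
  expect_true(is.na(daily_hkud(pts, lk)))
  pts26 <- kud_day(rnorm(26, 0, 30), rnorm(26, 0, 30))
  expect_false(is.na(daily_hkud(pts26, lk)))
})

test_that("degenerate single-point days return the one-cell area", {
  pts <- kud_day(rep(10, 30), rep(-20, 30))
  expect_equal(daily_hkud(pts, lk), 0.01)
})

test_that("dH-KUD matches the dense-grid oracle and orders cluster spread", {
  big <- tiny_lake(radius = 800)
  set.seed(42)
  one <- kud_day(rnorm(40, 0, 40), rnorm(40, 0, 40))
  two <- kud_day(c(rnorm(20, -450, 40), rnorm(20, 450, 40)),
                 rnorm(40, 0, 40))
  a_one <- daily_hkud(one, big)
  a_two <- daily_hkud(two, big)
  expect_gt(a_two, a_one)
  expect_equal(a_one, oracle_kud(one$x, one$y, big), tolerance = 0.01)
  expect_equal(a_two, oracle_kud(two$x, two$y, big), tolerance = 0.01)
})

test_that("dH-KUD area grows with the utilization level", {
  set.seed(7)
  pts <- kud_day(rnorm(30, 0, 60), rnorm(30, 0, 60))
  a50 <- daily_hkud(pts, lk, level = 0.50)
  a95 <- daily_hkud(pts, lk, level = 0.95)
  a99 <- daily_hkud(pts, lk, level = 0.99)
  expect_true(a50 <= a95 && a95 <= a99)
})

test_that("dH-KUD is translation invariant up to grid quantization", {
  set.seed(8)
  x <- rnorm(30, 0, 30); y <- rnorm(30, 0, 30)
  a <- daily_hkud(kud_day(x, y), lk)
  b <- daily_hkud(kud_day(x + 40, y - 30), lk)
  expect_equal(a, b, tolerance = 0.05)
})

test_that("in-lake kernel mass renormalizes to one", {
  # oracle reconstruction: sorted mass vector must sum to 1
  set.seed(9)
  pts <- kud_day(rnorm(30, 150, 60), rnorm(30, 0, 60))
  half <- floor(lk$radius / 10)
  g <- expand.grid(x = seq(-half, half) * 10, y = seq(-half, half) * 10)
  g <- g[g$x^2 + g$y^2 < lk$radius^2, ]
  dens <- 0
  for (i in seq_len(30))
    dens <- dens + exp(-((g$x - pts$x[i])^2 + (g$y - pts$y[i])^2) / 5000)
  expect_equal(sum(dens / sum(dens)), 1, tolerance = 1e-6)
})

test_that("dV-KS matches the closed form for equal depths and the oracle", {
  expect_equal(daily_vks(rep(7, 20)), 2 * qnorm(0.975) * 0.4,
               tolerance = 0.06)
  set.seed(3)
  shallow <- runif(40, 0, 3)
  deep <- runif(40, 0, 30)
  expect_gt(daily_vks(deep), daily_vks(shallow))
  expect_equal(daily_vks(deep), oracle_vks(deep), tolerance = 0.01)
  expect_equal(daily_vks(deep), daily_vks(rev(deep)))   # order invariance
  expect_true(is.na(daily_vks(5)))
})

test_that("activity converts displacement per 900 s, adjacent pairs only", {
  base <- as.POSIXct("2015-06-01 10:00:00", tz = "UTC")
  q <- qp(t = base + c(0, 900), x = c(0, 90), y = 0, depth = c(5, 14))
  act <- daily_activity(q, body_length = 100)
  expect_equal(act$horiz, 0.1)       # 90 m / 900 s / 1 m body length
  expect_equal(act$vert, 0.01)       # 9 m / 900 s
  # a third q-position two intervals later contributes nothing
  q3 <- qp(t = base + c(0, 900, 3600), x = c(0, 90, 1000), y = 0,
           depth = c(5, 14, 14))
  expect_equal(daily_activity(q3, 100)$horiz, 0.1)
  still <- qp(t = base + c(0, 900), x = 5, y = 5, depth = 3)
  expect_equal(daily_activity(still, 100), list(horiz = 0, vert = 0))
  expect_error(daily_activity(q, 0), "body_length")
})

test_that("time in open water uses the 5-m rule with >= 5 m pelagic", {
  expect_equal(daily_tow(c(1, 2, 7, 9))$tow, 0.5)
  all_b <- daily_tow(c(1, 2, 4.9))
  expect_equal(all_b$tow, 0)
  expect_true(all_b$all_benthic)
  expect_equal(daily_tow(5)$tow, 1)         # boundary value is open water
  expect_true(daily_tow(c(6, 8))$all_pelagic)
  expect_true(is.na(daily_tow(NA_real_)$tow))
})

test_that("simulated logger ropes give a stratified, seeded profile", {
  scn <- scenario_hsc()
  tmp <- make_temperature(scn, as.Date("2015-07-01"), noise_sd = 0, seed = 1)
  expect_setequal(unique(tmp$depth), c(0:13, 20))
  # warm epilimnion above the thermocline, cold hypolimnion below
  expect_gt(mean(tmp$temp[tmp$depth == 0]), mean(tmp$temp[tmp$depth == 13]))
  expect_lt(mean(tmp$temp[tmp$depth == 20]), 8)
  expect_identical(tmp, make_temperature(scn, as.Date("2015-07-01"),
                                         noise_sd = 0, seed = 1))
  daily <- daily_temperature(tmp)
  expect_equal(nrow(daily), 1)
  expect_gt(daily$temp, mean(tmp$temp))    # surface layer is the warmest
})

test_that("daily means, temperature and day length are simple summaries", {
  expect_equal(daily_mean_depth(c(2, 4)), 3)
  expect_equal(daily_mean_depth(c(7, NA)), 7)
  logg <- tibble::tibble(
    logger_id = "L", timestamp = as.POSIXct("2015-06-01 10:00", tz = "UTC"),
    depth = c(1, 2, 3, 5), temp = c(20, 18, 16, 8))
  out <- daily_temperature(logg)
  expect_equal(out$temp, 18)                # 5-m logger excluded
  tl <- day_length(flat_twilight("2015-06-01"))
  expect_equal(tl$day_length, 16)
  expect_true(all(day_length(make_twilight(
    seq(as.Date("2015-01-01"), by = 30, length.out = 12)))$day_length >= 0))
})
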