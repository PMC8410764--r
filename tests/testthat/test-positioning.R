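lk <- tiny_lake()

test_that("duplicate fixes collapse and boundary outliers are removed", {
  f <- fx(t = c("2015-06-01 12:00:00", "2015-06-01 12:00:00",
                "2015-06-01 12:00:25"),
          x = c(10, 10, 12), y = 0, depth = 2)
  out <- filter_positions(f, lk)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "removal_counts")[["duplicate"]], 1)

  far <- fx(t = c("2015-06-01 12:00:00", "2015-06-01 12:00:25"),
            x = c(0, lk$radius + 500), y = 0, depth = 2)
  out <- filter_positions(far, lk, boundary_buffer = 50)
  expect_equal(nrow(out), 1)
  expect_equal(out$x, 0)
  expect_warning(filter_positions(far, lake = NULL), "boundary rule skipped")
})

test_that("the neighbour-speed rule removes the displaced middle fix only", {
  # hand oracle: 300 m in 25 s = 12 m/s to both neighbours, > 2 m/s
  big <- tiny_lake(radius = 800)
  f <- fx(t = as.POSIXct("2015-06-01 12:00:00", tz = "UTC") + c(0, 25, 50),
          x = c(0, 100, 0), y = c(0, sqrt(300^2 - 100^2), 0), depth = 2)
  out <- filter_positions(f, big, max_speed = 2)
  expect_equal(nrow(out), 2)
  expect_equal(out$x, c(0, 0))
  expect_equal(attr(out, "removal_counts")[["speed"]], 1)
})

test_that("filtering is idempotent and tolerates empty input", {
  set.seed(4)
  f <- fx(t = as.POSIXct("2015-06-01", tz = "UTC") + seq(0, 7200, by = 25),
          x = cumsum(rnorm(289, 0, 5)), y = cumsum(rnorm(289, 0, 5)),
          depth = 3)
  once <- filter_positions(f, lk)
  twice <- filter_positions(once, lk)
  expect_equal(nrow(once), nrow(twice))
  expect_equal(once$x, twice$x)
  expect_equal(sum(attr(twice, "removal_counts")), 0)
  expect_equal(nrow(filter_positions(f[0, ], lk)), 0)
})

test_that("q-positions are interval means and depth-only intervals survive", {
  f <- fx(t = c("2015-06-01 12:01:00", "2015-06-01 12:05:00",
                "2015-06-01 12:20:00", "2015-06-01 12:25:00",
                "2015-06-01 12:28:00"),
          x = c(0, 10, NA, NA, NA), y = c(0, 0, NA, NA, NA),
          depth = c(4, 6, 7, 8, 9))
  q <- regularize(f)
  expect_equal(nrow(q), 2)
  expect_equal(q$x[1], 5)            # mean of (0, 10)
  expect_equal(q$y[1], 0)
  expect_equal(q$depth[1], 5)
  expect_true(is.na(q$x[2]))         # depth-only interval keeps its depth
  expect_equal(q$depth[2], 8)
  expect_equal(q$n_fixes, c(2L, 0L))
  expect_equal(q$n_depth_fixes, c(2L, 3L))
  expect_true(all(as.numeric(q$interval_start) %% 900 == 0))
})

test_that("full-coverage days give exactly 96 q-positions", {
  t <- as.POSIXct("2015-06-01", tz = "UTC") + seq(0, 86399, by = 25)
  f <- fx(t = t, x = 0, y = 0, depth = 5)
  q <- regularize(f)
  expect_equal(nrow(q), 96)
})

test_that("gaps are filled only under the time, distance and depth rules", {
  base <- as.POSIXct("2015-06-01 12:00:00", tz = "UTC")
  # qualifying gap: 45 min, 60 m, 1 m depth difference
  q <- qp(t = c(base, base + 2700), x = c(0, 60), y = 0, depth = c(5, 6))
  filled <- interpolate_gaps(q)
  expect_equal(nrow(filled), 4)
  ins <- filled[filled$interpolated, ]
  expect_equal(ins$x, c(20, 40))
  expect_equal(ins$y, c(0, 0))
  expect_equal(ins$depth, 5 + c(1, 2) / 3)
  expect_equal(ins$n_fixes, c(0L, 0L))

  # 3-h gap: condition (a) fails
  q <- qp(t = c(base, base + 3 * 3600), x = c(0, 60), y = 0, depth = c(5, 6))
  expect_equal(nrow(interpolate_gaps(q)), 2)
  # 150-m displacement: condition (b) fails
  q <- qp(t = c(base, base + 2700), x = c(0, 150), y = 0, depth = c(5, 6))
  expect_equal(nrow(interpolate_gaps(q)), 2)
  # 2-m depth difference is not "less than 2 m": condition (c) fails
  q <- qp(t = c(base, base + 2700), x = c(0, 60), y = 0, depth = c(5, 7))
  expect_equal(nrow(interpolate_gaps(q)), 2)
  # bounding q-position without coordinates: unevaluable, not filled
  q <- qp(t = c(base, base + 2700), x = c(NA, 60), y = c(NA, 0),
          depth = c(5, 6))
  expect_equal(nrow(interpolate_gaps(q)), 2)
})

test_that("interpolation is idempotent and conserves the segment", {
  base <- as.POSIXct("2015-06-01 06:00:00", tz = "UTC")
  q <- qp(t = base + c(0, 1800, 2700, 6300), x = c(0, 30, 35, 80),
          y = c(0, 40, 42, 60), depth = c(5, 5.5, 5.6, 6.5))
  f1 <- interpolate_gaps(q)
  f2 <- interpolate_gaps(f1)
  expect_equal(f1, f2)
  # every filled point lies on the segment between its bounding q-positions
  ins <- f1[f1$interpolated, ]
  expect_equal(nrow(f1) - nrow(q), sum((diff(as.numeric(q$interval_start)) /
                                          900 - 1)))
  for (i in seq_len(nrow(ins))) {
    before <- q[q$interval_start < ins$interval_start[i], ]
    after <- q[q$interval_start > ins$interval_start[i], ]
    P <- before[nrow(before), ]; Q <- after[1, ]
    cross <- (Q$x - P$x) * (ins$y[i] - P$y) - (Q$y - P$y) * (ins$x[i] - P$x)
    expect_equal(cross, 0, tolerance = 1e-9)
  }
})

test_that("distance to bottom subtracts sensor depth, averaging per fix", {
  r10 <- lk$radius * sqrt(0.5)              # bottom depth exactly 10 m here
  q <- qp(t = "2015-06-01 12:00:00", x = r10, y = 0, depth = 3)
  out <- distance_to_bottom(q, lk)
  expect_equal(out$dist_to_bottom, 7)
  q$depth <- 10
  expect_equal(distance_to_bottom(q, lk)$dist_to_bottom, 0)

  # two fixes in one interval with per-fix distances 4 and 6 -> mean 5
  r16 <- lk$radius * sqrt(1 - 16 / 20)      # bottom 16 m
  r12 <- lk$radius * sqrt(1 - 12 / 20)      # bottom 12 m
  f <- fx(t = c("2015-06-01 12:01:00", "2015-06-01 12:08:00"),
          x = c(r16, r12), y = 0, depth = c(10, 8))
  q <- regularize(f)
  out <- distance_to_bottom(q, lk, fixes = f)
  expect_equal(out$dist_to_bottom, 5)
  # the q-position-level value would differ (bottom at the mean position)
  naive <- distance_to_bottom(q, lk)
  expect_false(isTRUE(all.equal(naive$dist_to_bottom, 5)))

  # beyond the shoreline: kept, NA, warning
  q_out <- qp(t = "2015-06-01 12:00:00", x = lk$radius + 5, y = 0, depth = 1)
  expect_warning(out <- distance_to_bottom(q_out, lk), "shoreline")
  expect_true(is.na(out$dist_to_bottom))
})

test_that("mortality flagging finds terminal stillness only", {
  base <- as.POSIXct("2015-06-01", tz = "UTC")
  t <- base + 900 * (0:767)                 # 8 days of q-positions
  set.seed(1)
  live <- qp(t = t, x = cumsum(rnorm(768, 0, 8)),
             y = cumsum(rnorm(768, 0, 8)), depth = 5 + rnorm(768, 0, 1))
  v <- flag_mortality(live)
  expect_false(v$flagged)

  # moving 3 days, then constant for the final 5 days
  dead <- live
  dead$x[289:768] <- 600; dead$y[289:768] <- -600; dead$depth[289:768] <- 18
  v <- flag_mortality(dead)
  expect_true(v$flagged)
  expect_equal(v$truncation_time, dead$interval_start[289])

  # still for 24 h in the middle, then movement resumes: not flagged
  pause <- live
  pause$x[200:296] <- 0; pause$y[200:296] <- 0; pause$depth[200:296] <- 6
  expect_false(flag_mortality(pause)$flagged)
})
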