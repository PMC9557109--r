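test_that("daily GDD follows the mean-temperature formula with zero clipping", {
  expect_equal(daily_gdd(30, 20), 15)
  expect_equal(daily_gdd(35.2, 24.8), 20)
  expect_equal(daily_gdd(12, 6), 0)      # mean 9 < base 10: clipped
  expect_equal(daily_gdd(c(30, 12), c(20, 6)), c(15, 0))
  expect_error(daily_gdd(10, 20), "tmax < tmin")
})

test_that("accumulated GDD matches a day-by-day loop oracle on random series", {
  set.seed(41)
  for (k in 1:5) {
    w <- constant_weather("2020-06-01", 60)
    w$tmax_c <- w$tmax_c + rnorm(60, 0, 4)
    w$tmin_c <- pmin(w$tmin_c + rnorm(60, 0, 4), w$tmax_c - 0.1)
    start <- w$date[1]; end <- w$date[60]
    oracle <- 0
    for (i in 2:60) oracle <- oracle + max(0, (w$tmax_c[i] + w$tmin_c[i]) / 2 - 10)
    expect_equal(accumulate_gdd(w, start, end), oracle)
  }
})

test_that("accumulated GDD handles empty windows, gaps and constant weather", {
  w <- constant_weather("2020-06-01", 10, tmean = 25)  # 15 degC d per day
  expect_equal(accumulate_gdd(w, w$date[1], w$date[10]), 9 * 15)
  expect_equal(accumulate_gdd(w, w$date[1], w$date[1]), 0)
  expect_error(accumulate_gdd(w, w$date[1], w$date[10] + 5), "gaps")
})

test_that("accumulation is additive, monotone and bounded below by zero", {
  set.seed(99)
  w <- constant_weather("2020-06-01", 90)
  w$tmax_c <- w$tmax_c + rnorm(90, 0, 6)
  w$tmin_c <- pmin(w$tmin_c + rnorm(90, 0, 6), w$tmax_c)
  a <- w$date[1]; c <- w$date[90]
  for (b in w$date[c(10, 45, 80)]) {
    expect_equal(accumulate_gdd(w, a, b) + accumulate_gdd(w, b, c),
                 accumulate_gdd(w, a, c))
  }
  expect_gte(accumulate_gdd(w, a, c), 0)
  # appending a warm day strictly increases the sum
  w2 <- rbind(w, data.frame(year = 2020, date = c + 1, tmax_c = 30, tmin_c = 20))
  expect_gt(accumulate_gdd(w2, a, c + 1), accumulate_gdd(w, a, c))
})

test_that("stage durations split the season at silking and reconcile", {
  # published 2019 early-hybrid dates: sowing 6/16, R1 8/1, R6 10/3
  w <- constant_weather("2019-06-01", 140, year = 2019)
  rec <- list(year = 2019, hybrid = "DH518", sowing = "2019-06-16",
              r1 = "2019-08-01", r6 = "2019-10-03")
  sd <- stage_durations(rec, w)
  expect_equal(sd$days_before_silking, 46)
  expect_equal(sd$days_after_silking, 63)
  expect_equal(sd$total_days, 109)
  expect_equal(sd$total_gdd, sd$gdd_before_silking + sd$gdd_after_silking)
  # constant 25 degC weather: GDD = days x (mean - base)
  expect_equal(sd$gdd_before_silking, 46 * 15)
  expect_equal(sd$gdd_after_silking, 63 * 15)
  # degenerate: all stages on one day
  rec0 <- list(year = 2019, hybrid = "x", sowing = "2019-07-01",
               r1 = "2019-07-01", r6 = "2019-07-01")
  sd0 <- stage_durations(rec0, w)
  expect_equal(unlist(sd0[3:8], use.names = FALSE), rep(0, 6))
})

test_that("yield per GDD is the plain ratio with a positive-GDD domain", {
  expect_equal(yield_per_gdd(1500, 1500), 1)
  expect_equal(yield_per_gdd(12745.4, 1001.2), 12.73, tolerance = 1e-3)
  expect_equal(yield_per_gdd(0, 1000), 0)
  expect_error(yield_per_gdd(1000, 0), "positive")
})
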