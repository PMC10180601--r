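test_that("window definitions: vegetation period and previous winter", {
  vp <- vegetation_period(1995)
  expect_equal(vp$start, as.Date("1995-04-01"))
  expect_equal(vp$end, as.Date("1995-09-30"))
  pw <- previous_winter(1995)
  expect_equal(pw$start, as.Date("1994-10-01"))
  expect_equal(pw$end, as.Date("1995-03-31"))
})

test_that("aggregation: means, sums, actual calendar day counts", {
  d <- make_daily(1995, tmean = 10, ppt = 1)
  expect_equal(aggregate_period(d, vegetation_period(1995), "tmean", "mean"), 10)
  # Apr-Sep has 183 days
  expect_equal(aggregate_period(d, vegetation_period(1995), "ppt", "sum"), 183)
  # leap year: 1996 VP still 183 days but PW(1996) spans 183 days too
  d2 <- make_daily(1995:1996, ppt = 1)
  expect_equal(aggregate_period(d2, previous_winter(1996), "ppt", "sum"), 183)
})

test_that("aggregation enforces the missing-day tolerance", {
  d <- make_daily(1995, tmean = 10)
  d_gappy <- d[-(100:130), ] # remove a month of days
  expect_error(
    aggregate_period(d_gappy, vegetation_period(1995), "tmean", "mean"),
    "missing"
  )
  # a couple of missing days are tolerated
  d_ok <- d[-(150:151), ]
  expect_equal(
    aggregate_period(d_ok, vegetation_period(1995), "tmean", "mean"), 10
  )
})

test_that("heat sum adds exceedances above 20 C with a strict threshold", {
  d <- make_daily(1995)
  d$tmean[1:4] <- c(21, 25, 19, 20)
  d$tmean[-(1:4)] <- 15
  expect_equal(heat_sum(d, month_window(1995, 1)), 6.0)
  d$tmean <- 20
  expect_equal(heat_sum(d, vegetation_period(1995)), 0)
})

test_that("threshold day counts use inclusive temperature, exclusive rain bounds", {
  d <- make_daily(1995)
  d$tmax[1:2] <- c(30.0, 29.9)
  expect_equal(threshold_day_count(d, month_window(1995, 1), "hot"), 1)

  d$ppt[1:2] <- c(1.0, 1.1)
  expect_equal(threshold_day_count(d, month_window(1995, 1), "rain"), 1)

  d$tmin[1:3] <- c(0, -1, 0.1)
  expect_equal(threshold_day_count(d, month_window(1995, 1), "frost"), 2)

  dw <- make_daily(1995, tmax = -1)
  expect_equal(
    threshold_day_count(dw, month_window(1995, 1), "ice"), 31
  )
})

test_that("vapour pressure deficit follows the Magnus formula", {
  expect_equal(vpd(25, 100), 0)
  expect_equal(vpd(15, 0), saturation_vp(15))
  # T = 20 C, rh = 50 %: e_s ~ 23.4 hPa, vpd ~ 11.7 hPa
  expect_equal(saturation_vp(20), 6.1078 * exp(17.27 * 20 / 257.3))
  expect_equal(saturation_vp(20), 23.4, tolerance = 0.01)
  expect_equal(vpd(20, 50), 11.7, tolerance = 0.01)
  expect_error(vpd(20, 101), "rh")
})

test_that("vpd is monotone: decreasing in rh, increasing in temperature", {
  rh <- seq(0, 100, by = 5)
  expect_true(all(diff(vpd(20, rh)) < 0))
  tt <- seq(-10, 35, by = 1)
  expect_true(all(diff(vpd(tt, 50)) > 0))
  expect_true(all(vpd(tt, 30) >= 0))
})

test_that("daily maximum VPD comes from sub-daily samples when available", {
  sub <- tibble::tibble(
    datetime = as.POSIXct("1995-07-01 00:00", tz = "UTC") + seq(0, 86399, 600),
    temp = 15 + 10 * sin(pi * seq(0, 1, length.out = 144)),
    rh = 80 - 30 * sin(pi * seq(0, 1, length.out = 144))
  )
  dm <- daily_max_vpd(sub)
  expect_equal(nrow(dm), 1L)
  expect_equal(dm$vpd_max, max(vpd(sub$temp, sub$rh)))
})

test_that("Thornthwaite PET matches the hand-evaluated formula", {
  monthly <- tibble::tibble(year = 2000, month = 1:12, tmean = 10)
  # with correction L = 1: I ~ 34.27, a ~ 1.043, PET ~ 48.9 mm/month
  pet <- thornthwaite_pet(monthly, latitude = 50, correction = rep(1, 12))
  expect_equal(pet$pet, rep(48.9, 12), tolerance = 0.01)

  # months at or below 0 C evaporate nothing
  monthly$tmean <- c(-5, 0, rep(10, 10))
  pet <- thornthwaite_pet(monthly, latitude = 50, correction = rep(1, 12))
  expect_equal(pet$pet[1:2], c(0, 0))

  # warmer months have larger PET at the same latitude correction
  monthly$tmean <- 1:12
  pet <- thornthwaite_pet(monthly, latitude = 50, correction = rep(1, 12))
  expect_true(all(diff(pet$pet) > 0))

  expect_error(
    thornthwaite_pet(
      tibble::tibble(year = 2000, month = 1:12, tmean = -3),
      latitude = 50
    ),
    "zero"
  )
})

test_that("annual PET increases when every month warms", {
  monthly <- tibble::tibble(
    year = 2000, month = 1:12,
    tmean = c(-1, 0, 4, 8, 13, 16, 18, 17, 13, 8, 3, 0)
  )
  p1 <- sum(thornthwaite_pet(monthly, latitude = 49.93)$pet)
  monthly$tmean <- monthly$tmean + 2
  p2 <- sum(thornthwaite_pet(monthly, latitude = 49.93)$pet)
  expect_gt(p2, p1)
  expect_true(all(thornthwaite_pet(monthly, latitude = 49.93)$pet >= 0))
})

test_that("climate index table carries the defined variable-window pairs", {
  d <- make_daily(1994:1996, tmean = 12, rh = 70)
  d$ppt <- c(2, 2.1, 1.9)[as.integer(format(d$date, "%Y")) - 1993]
  suppressWarnings(idx <- climate_indices(d))
  expect_true(all(
    c("year", "variable", "window", "value") %in% names(idx)
  ))
  # nid is defined monthly and for PW, but not VP
  expect_false(any(idx$variable == "nid" & idx$window == "VP"))
  # hs has no PW window
  expect_false(any(idx$variable == "hs" & idx$window == "PW"))
  # constant 12 C, rain 2 mm daily: VP tmean 12, VP ppt = 183 * 2
  vp95 <- idx[idx$year == 1995 & idx$window == "VP", ]
  expect_equal(vp95$value[vp95$variable == "tmean"], 12)
  expect_equal(vp95$value[vp95$variable == "ppt"], 183 * 2.1)
  expect_equal(vp95$value[vp95$variable == "nrd"], 183)
  # first-year PW is incomplete -> NA
  expect_true(is.na(idx$value[
    idx$year == 1994 & idx$window == "PW" & idx$variable == "tmean"
  ]))
})
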