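# Solar geometry: sunrise/sunset and the night-length series.

test_that("daylight is about 12 h at the equator and at an equinox", {
  eq <- city_config("equator", 0, 0, 0, 1e5)
  ev <- sun_events(eq, as.Date("2007-06-21"))
  expect_lt(abs((ev$sunset - ev$sunrise) - 12), 0.2)

  ev <- sun_events(city40, as.Date("2007-03-20"))
  expect_lt(abs((ev$sunset - ev$sunrise) - 12), 0.25)
})

test_that("sunrise/sunset match an independent high-precision ephemeris", {
  # Reference values computed with a separate Julian-day NOAA/Meeus
  # implementation (independent code path, Python), lon 0, UTC:
  #   40N 2007-06-21: rise 4.5196, set 19.5369
  #   37N 2007-06-21: rise 4.6753, set 19.3812
  #   40N 2007-12-22: rise 7.3099, set 16.6375
  tol <- 2 / 60  # two minutes
  ev <- sun_events(city40, as.Date("2007-06-21"))
  expect_lt(abs(ev$sunrise - 4.5196), tol)
  expect_lt(abs(ev$sunset - 19.5369), tol)
  ev37 <- sun_events(city37, as.Date("2007-06-21"))
  expect_lt(abs(ev37$sunrise - 4.6753), tol)
  expect_lt(abs(ev37$sunset - 19.3812), tol)
  # midsummer daylight is longer at 40N than at 37N
  expect_gt(ev$sunset - ev$sunrise, ev37$sunset - ev37$sunrise)
  evw <- sun_events(city40, as.Date("2007-12-22"))
  expect_lt(abs(evw$sunrise - 7.3099), tol)
  expect_lt(abs(evw$sunset - 16.6375), tol)
})

test_that("night length peaks at the winter solstice and bottoms at the summer solstice", {
  nl <- night_length_series(city40, 2007)
  expect_identical(nl$d[which.max(nl$n_length)], 356L)
  expect_identical(nl$d[which.min(nl$n_length)], 172L)
  expect_true(all(nl$n_length > 0 & nl$n_length < 24))
  # night + daylight = 24 by construction
  expect_equal(nl$n_length + (nl$sunset - nl$sunrise), rep(24, 365),
               tolerance = 1e-9)
})

test_that("the series is unimodal and photoperiod amplitude grows with latitude", {
  nl <- night_length_series(city40, 2007)
  # increasing from the summer solstice to the winter solstice, and
  # decreasing from new year to the summer solstice (2-day jitter allowed)
  rising <- nl$n_length[174:354]
  expect_true(all(diff(rising) > -1e-6))
  falling <- nl$n_length[3:170]
  expect_true(all(diff(falling) < 1e-6))

  r37 <- diff(range(night_length_series(city37, 2007)$n_length))
  r42 <- diff(range(night_length_series(city42, 2007)$n_length))
  expect_gt(r42, r37)

  # winter-solstice night length strictly increases with latitude
  v <- sapply(seq(36, 44, 2), function(la)
    night_length_series(city_config("x", la, 0, 0, 1e5), 2007)$n_length[356])
  expect_true(all(diff(v) > 0))
})

test_that("polar latitudes and leap years are rejected", {
  expect_error(night_length_series(city_config("polar", 70, 0, 0, 1e5)),
               "unsupported latitude")
  expect_error(sun_events(city_config("polar", -80, 0, 0, 1e5),
                          as.Date("2007-06-21")),
               "unsupported latitude")
  expect_error(night_length_series(city40, 2008), "leap")
  expect_error(city_config("bad", 95, 0, 0, 1e5), "latitude")
})
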