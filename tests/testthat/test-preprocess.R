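# User filters, logical-day assignment, binning and smoothing.

test_that("geographic assignment applies both closeness rules strictly", {
  u <- rbind(
    user_at("ok", city40, mact_km = 5, postal_km = 7),     # both rules hold
    user_at("far_center", city40, mact_km = 16, postal_km = -16),
    user_at("far_apart", city40, mact_km = 10, postal_km = 10 + 35)
  )
  kept <- assign_users_to_city(u, city40)
  expect_identical(kept$user_id, "ok")
  dc <- attr(kept, "drop_counts")
  expect_identical(unname(dc["center_rule"]), 1L)
  expect_identical(unname(dc["separation_rule"]), 1L)

  # missing location discards the user
  u$mact_lat[1] <- NA
  expect_identical(nrow(assign_users_to_city(u, city40)), 0L)

  # order-independent and idempotent
  u2 <- rbind(user_at("a", city40, 1, 2), user_at("b", city40, 20, 20),
              user_at("c", city40, 3, 1))
  k1 <- assign_users_to_city(u2, city40)
  k2 <- assign_users_to_city(u2[c(3, 1, 2), ], city40)
  expect_setequal(k1$user_id, k2$user_id)
  expect_identical(assign_users_to_city(k1, city40)$user_id, k1$user_id)
})

test_that("age filter is a closed 30-75 interval", {
  u <- data.frame(user_id = letters[1:5], age = c(29, 30, 50, 75, 76))
  expect_identical(filter_age(u)$user_id, c("b", "c", "d"))
  expect_identical(unname(attr(filter_age(u), "drop_counts")), 2L)
})

test_that("haversine matches the meridian arc on the 6371 km sphere", {
  expect_equal(haversine_km(0, 0, 1, 0), 2 * pi * 6371 / 360,
               tolerance = 1e-6)
})

test_that("calls map to logical days on the extended 4-28 h axis", {
  calls <- data.frame(
    user_id = c("u1", "u1", "u1"),
    timestamp = c("2007-02-15T03:30:00+0000",   # before 4 am -> previous day
                  "2007-02-15T04:00:00+0000",   # boundary -> same day
                  "2007-01-01T02:00:00+0000"))  # belongs to d = 0 -> dropped
  lc <- logical_day(calls, city40, 2007)
  expect_identical(lc$d, c(45L, 46L))
  expect_equal(lc$t, c(27.5, 4.0))
  expect_identical(attr(lc, "dropped"), 1L)

  # the city's UTC offset defines local time
  east <- city_config("east", 40, 15, 1, 1e5)
  lc2 <- logical_day(data.frame(user_id = "u", timestamp = "2007-02-15T03:30:00+0100"),
                     east, 2007)
  expect_identical(lc2$d, 45L)
  expect_equal(lc2$t, 27.5)
})

test_that("atypical-day rule flags planted outliers and nothing else", {
  vols <- data.frame(d = 1:63, n = 100 + rep(c(0, 2, -2), 21))
  expect_identical(detect_atypical_days(vols), integer(0))
  vols$n[30] <- 1000
  expect_identical(detect_atypical_days(vols), 30L)
  expect_identical(detect_atypical_days(vols, k = Inf), integer(0))
  expect_error(detect_atypical_days(vols[1:20, ]), "8 weeks")
})

test_that("windows bin to the documented grid and conserve events", {
  expect_length(bin_and_smooth(numeric(0), "morning")$counts, 132)
  expect_length(bin_and_smooth(numeric(0), "night")$counts, 132)
  expect_length(bin_and_smooth(numeric(0), "full")$counts, 288)

  set.seed(1)
  t <- runif(500, 17, 28)
  h <- bin_and_smooth(t, "night", smooth = FALSE)
  expect_identical(sum(h$counts), 500L)
  expect_error(bin_and_smooth(16.5, "night"), "outside")
})

test_that("Savitzky-Golay (7,4) is exact on low-degree polynomials and conserves mass", {
  expect_equal(sg_smooth(rep(3, 50)), rep(3, 50), tolerance = 1e-9)

  x <- seq(-1, 1, length.out = 60)
  quartic <- 5 + x - 2 * x^2 + 0.5 * x^3 + x^4
  sm <- sg_smooth(quartic, clip = FALSE)
  expect_equal(sm[4:57], quartic[4:57], tolerance = 1e-9)

  spike <- rep(0, 132); spike[60] <- 1
  expect_equal(sum(sg_smooth(spike, clip = FALSE)), 1, tolerance = 1e-6)
})
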