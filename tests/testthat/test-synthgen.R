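# Synthetic generator: temperatures, cohorts, calibrated call streams.

test_that("temperature generator: cosine seasonality, determinism, edge cases", {
  city <- city40
  flat <- generate_temperatures(city, amplitude = 0, noise_sd = 0, seed = 1)
  expect_true(all(flat$theta == 20))

  t1 <- generate_temperatures(city, seed = 9)
  t2 <- generate_temperatures(city, seed = 9)
  expect_identical(t1$theta, t2$theta)

  clean <- generate_temperatures(city, mean = 20, amplitude = 12,
                                 noise_sd = 0, seed = 1)
  expect_identical(clean$d[which.max(clean$theta)], 202L)
  expect_equal(max(clean$theta), 32, tolerance = 1e-9)
})

test_that("cohort generator plants exactly the requested violations", {
  expect_identical(nrow(generate_users(city40, 0)$users), 0L)

  all_ok <- generate_users(city40, 200, frac_invalid = 0, seed = 3)
  kept <- filter_age(assign_users_to_city(all_ok$users, city40))
  expect_identical(nrow(kept), 200L)

  mixed <- generate_users(city40, 1000, frac_invalid = 0.3, seed = 4)
  kept <- filter_age(assign_users_to_city(mixed$users, city40))
  planted_valid <- mixed$truth$user_id[mixed$truth$valid]
  expect_setequal(kept$user_id, planted_valid)
  expect_identical(length(planted_valid), 700L)
  # each violation type actually trips its own filter
  expect_identical(sort(unique(mixed$truth$violation)),
                   c("age_range", "far_center", "far_separation", "none"))
})

test_that("call generator is deterministic, windowed, and truth-consistent", {
  city <- city_config("synthville", 40, 0, 1, 6e5)
  nl <- night_length_series(city)
  tmp <- generate_temperatures(city, seed = 11)
  p <- synth_params()
  u <- generate_users(city, 50, seed = 5)$users

  g1 <- generate_calls(city, u, 2007, nl, tmp, p, seed = 2, days = 5:6)
  g2 <- generate_calls(city, u, 2007, nl, tmp, p, seed = 2, days = 5:6)
  expect_identical(g1$calls, g2$calls)
  expect_gt(nrow(g1$calls), 0)

  # no calls at rate zero, but a valid truth channel
  g0 <- generate_calls(city, u, 2007, nl, tmp, synth_params(lambda = 0),
                       seed = 2, days = 5:6)
  expect_identical(nrow(g0$calls), 0L)
  expect_identical(g0$truth$daily$d, 5:6)
  expect_true(all(is.finite(g0$truth$daily$t_night_true)))

  # emitted timestamps map back into the assigned logical days
  lc <- logical_day(g1$calls, city, 2007)
  expect_true(all(lc$t >= 4 & lc$t < 28))
  expect_true(all(lc$d %in% 5:7))          # boundary rounding may spill 1 day
  expect_gte(mean(lc$d %in% 5:6), 0.99)

  # truth invariants
  tr <- g1$truth$daily
  expect_true(all(tr$t_night_true > 0 & tr$t_night_true < 24))
  expect_true(all(tr$t_break_true >= 0 & tr$t_break_true < 11))
})

test_that("calibrated centres reproduce the estimator-side targets", {
  city <- city_config("synthville", 40, 0, 1, 6e5)
  nl <- night_length_series(city)
  tmp <- generate_temperatures(city, seed = 11)
  p <- synth_params()
  g <- generate_calls(city, data.frame(user_id = character(0)), 2007,
                      nl, tmp, p, seed = 1, days = c(40, 200))
  sds <- c(p$s_F, p$sigma_M, p$sigma_N, p$s_L)
  for (i in seq_len(nrow(g$truth$daily))) {
    row <- g$truth$daily[i, ]
    st <- restcdr:::.pop_day_stats(c(row$mu_F, row$t_M, row$t_N, row$mu_L),
                                   sds, p$w, p$lambda, smooth = TRUE,
                                   with_break = TRUE)
    expect_lt(abs(st$F_stat - row$target_F), 0.02)
    expect_lt(abs(st$L_stat - row$target_L), 0.02)
    expect_lt(abs(st$t_break - row$t_break_true), 0.05)
    # the realized population T_night equals the truth formula
    expect_lt(abs((24 - st$L_stat + row$target_F) -
                  (24 - row$target_L + row$target_F)), 0.02)
  }
})

test_that("conserved mode zeroes the temperature response of total rest", {
  city <- city_config("synthville", 40, 0, 1, 6e5)
  nl <- night_length_series(city)
  tmp <- generate_temperatures(city, seed = 11)
  p <- synth_params(conserved = TRUE)
  expect_identical(p$c_night, p$c_break)
  g <- generate_calls(city, data.frame(user_id = character(0)), 2007,
                      nl, tmp, p, seed = 1, days = c(30, 31, 200, 201))
  tr <- g$truth$daily
  resid <- (tr$t_night_true + tr$t_break_true) -
    (p$a_night + p$e_break + p$b_night * tr$n_length)
  expect_equal(stats::var(resid), 0, tolerance = 1e-20)
})
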