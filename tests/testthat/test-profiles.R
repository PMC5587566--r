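# Activity profiles, the T_night statistic and weekly aggregation.

fab_profile <- function(mean, sd, valid = TRUE) {
  structure(list(mean = mean, sd = sd, valid = valid),
            class = "activity_profile")
}

test_that("per-user reduction keeps one first-morning and one last-night call", {
  dc <- data.table::data.table(
    user_id = c("a", "a", "a", "a", "b", "c"),
    d = 10L,
    t = c(8.0, 9.5, 18.0, 26.5, 16.5, 7.25))
  fl <- first_last_events(dc)
  expect_equal(fl$first[fl$first$user_id == "a"]$t, 8.0)
  expect_equal(fl$last[fl$last$user_id == "a"]$t, 26.5)
  # a call in the afternoon gap contributes to neither window
  expect_false("b" %in% fl$first$user_id)
  expect_false("b" %in% fl$last$user_id)
  expect_equal(fl$first[fl$first$user_id == "c"]$t, 7.25)
})

test_that("profile moments recover distribution parameters", {
  # all mass in one bin: degenerate, mean at the bin centre
  p <- build_profile(rep(22.02, 60), "night", smooth = FALSE)
  expect_true(p$degenerate)
  expect_equal(p$mean, 22 + 1 / 24, tolerance = 1e-9)

  # uniform mass over the night window: mean at the midpoint
  p <- build_profile(seq(17.001, 27.999, length.out = 5000), "night")
  expect_equal(p$mean, 22.5, tolerance = 0.05)

  # Monte-Carlo: N(22, 1) truncated to the night window
  set.seed(42)
  x <- rnorm(1e4, 22, 1)
  x <- x[x >= 17 & x < 28]
  p <- build_profile(x, "night")
  expect_equal(p$mean, 22.0, tolerance = 0.05)
  expect_equal(p$sd, 1.0, tolerance = 0.05)

  # below the validity threshold
  expect_false(build_profile(rep(20, 10), "night")$valid)

  # smoothing preserves normalization
  expect_equal(sum(p$density), 1, tolerance = 1e-6)
})

test_that("T_night follows the moment formula on the extended axis", {
  expect_equal(t_night(fab_profile(23, 0), fab_profile(9, 0)), 10.0)
  expect_equal(t_night(fab_profile(22.8, 0.7), fab_profile(9.0, 1.0)), 8.5)
  expect_true(is.na(t_night(fab_profile(23, 0.5, valid = FALSE),
                            fab_profile(9, 0.5))))

  # strictly decreasing in either spread
  base <- t_night(fab_profile(23, 0.5), fab_profile(9, 0.5))
  expect_lt(t_night(fab_profile(23, 0.9), fab_profile(9, 0.5)), base)
  expect_lt(t_night(fab_profile(23, 0.5), fab_profile(9, 0.9)), base)
})

test_that("weekly aggregates split Mon-Thu from Fri-Sun and respect gaps", {
  # 2007 starts on a Monday; build two full weeks
  d <- 1:14
  wd <- as.integer(weekday_labels(d))
  v <- ifelse(wd <= 4, 10, 9)
  agg <- weekly_aggregates(data.frame(d = d, t_night = v))
  expect_equal(agg$mon_thu, c(10, 10))
  expect_equal(agg$fri_sun, c(9, 9))

  # constant series -> the constant back
  agg <- weekly_aggregates(data.frame(d = 1:21, t_night = 7.5))
  expect_true(all(agg$mon_thu == 7.5 & agg$fri_sun == 7.5))

  # an excluded Tuesday leaves the mean over the remaining three weekdays
  v <- rep(10, 14); v[wd <= 4] <- c(10, 12, 10, 12, 10, 12, 10, 12)
  v[2] <- NA  # Tuesday of week 1
  agg <- weekly_aggregates(data.frame(d = d, t_night = v))
  expect_equal(agg$mon_thu[1], mean(c(10, 10, 12)))
})
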