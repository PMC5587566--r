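# Two-regime clustering of the temperature / afternoon-break scatter.

planted_clouds <- function(seed = 1, n_cold = 150, n_warm = 120) {
  set.seed(seed)
  theta <- c(runif(n_cold, 5, 18), runif(n_warm, 24, 38))
  tb <- c(rnorm(n_cold, 4.5, 0.05),
          4.5 + 0.05 * (theta[(n_cold + 1):(n_cold + n_warm)] - 22) +
            rnorm(n_warm, 0, 0.05))
  list(theta = theta, t_break = tb,
       regime = rep(c("cold", "warm"), c(n_cold, n_warm)))
}

test_that("well-separated regimes are recovered almost perfectly", {
  pc <- planted_clouds(seed = 1)
  cl <- cluster_two_regimes(pc$theta, pc$t_break, seed = 1)
  expect_gte(mean(as.character(cl$labels) == pc$regime), 0.95)
  expect_false(cl$low_confidence)

  # agreement with an independent spectral-clustering implementation
  set.seed(1)
  km <- kernlab::specc(scale(cbind(pc$theta, pc$t_break)), centers = 2)
  lab_k <- ifelse(km@.Data == km@.Data[1], pc$regime[1],
                  setdiff(c("cold", "warm"), pc$regime[1]))
  expect_gte(mean(lab_k == as.character(cl$labels)), 0.9)
})

test_that("labels are invariant under permutation of the input order", {
  pc <- planted_clouds(seed = 3)
  perm <- sample(length(pc$theta))
  cl1 <- cluster_two_regimes(pc$theta, pc$t_break, seed = 1)
  cl2 <- cluster_two_regimes(pc$theta[perm], pc$t_break[perm], seed = 1)
  expect_identical(as.character(cl2$labels), as.character(cl1$labels)[perm])
})

test_that("a single compact cloud is reported with low confidence", {
  set.seed(4)
  cl <- cluster_two_regimes(rnorm(120, 15, 1), rnorm(120, 4.5, 0.1), seed = 1)
  expect_true(cl$low_confidence)
  expect_lt(cl$silhouette, 0.4)
  expect_error(cluster_two_regimes(rep(10, 40), rep(4.5, 40)), "identical")
})

test_that("percentile rule gives the midpoint for separated clusters", {
  theta <- c(seq(10, 20, 1), rep(20, 60), rep(24, 60), seq(25, 35, 1))
  labels <- factor(rep(c("cold", "warm"), each = 71),
                   levels = c("cold", "warm"))
  expect_equal(threshold_temperature(theta, labels, method = "percentile"), 22)
  expect_equal(threshold_temperature(theta, labels, method = "min_warm"), 24)
})

test_that("threshold recovery is unbiased and ordered across true thresholds", {
  est22 <- vapply(1:5, function(s) {
    sc <- simulate_break_scatter(theta_star = 22, break_noise_sd = 0.15,
                                 seed = s)
    cl <- cluster_two_regimes(sc$theta, sc$t_break, seed = 1)
    threshold_temperature(sc$theta, cl$labels, sc$t_break)
  }, numeric(1))
  expect_lt(abs(mean(est22) - 22), 2)

  ordered <- vapply(1:10, function(s) {
    est <- vapply(c(18, 25), function(tstar) {
      sc <- simulate_break_scatter(theta_star = tstar, break_noise_sd = 0.15,
                                   seed = s)
      cl <- cluster_two_regimes(sc$theta, sc$t_break, seed = 1)
      threshold_temperature(sc$theta, cl$labels, sc$t_break)
    }, numeric(1))
    est[1] < est[2]
  }, logical(1))
  expect_true(all(ordered))
})

test_that("regime correlations split at the threshold and degrade gracefully", {
  pc <- planted_clouds(seed = 6)
  rc <- regime_correlations(pc$theta, pc$t_break, 22)
  expect_lt(abs(rc$r_below), 0.25)
  expect_gt(rc$r_above, 0.5)

  # zero-noise linear warm regime: perfect correlation
  th <- seq(23, 35, 0.5)
  rc <- regime_correlations(th, 4.5 + 0.05 * (th - 22), 23)
  expect_equal(rc$r_above, 1, tolerance = 1e-10)
  expect_identical(rc$n_below, 0L)
  expect_true(is.na(rc$r_below))

  # theta* = +Inf reproduces the all-points correlation on the cold side
  rc_all <- regime_correlations(pc$theta, pc$t_break, Inf)
  expect_equal(rc_all$r_below, cor(pc$theta, pc$t_break), tolerance = 1e-12)
})
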