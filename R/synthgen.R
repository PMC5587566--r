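# Synthetic call-record generator with a ground-truth channel.
#
# One synthetic day is a four-component Gaussian intensity on the extended
# axis [4, 28): a wake component (centre mu_F), the noon activity mode
# (t_M), the evening activity mode (t_N) and a bedtime component (mu_L).
# Every call of every user on day d is an i.i.d. draw from this density,
# with a Poisson(lambda) number of calls per user-day. Because calls are a
# thinned Poisson process, the population distributions of each user's
# first morning call and last night call follow in closed form:
#     p_F(t) ~ lambda g(t) exp(-lambda G_[5,t]),
#     p_L(t) ~ lambda g(t) exp(-lambda G_[t,28)),
# so the generator can *calibrate* the component centres per day such that
# the estimator's population values of T_night (window moments of p_L, p_F)
# and T_break (two-Gaussian fit of the full-day profile) equal the
# ground-truth formulas
#     T_night(d) = a + b N_length(d) - c_night max(0, theta(d) - theta*),
#     T_break(d) = e + c_break max(0, theta(d) - theta*).
# The calibration measures the gaps exactly as the pipeline does (5-minute
# bins, Savitzky-Golay smoothing), keeping the recovery problem well posed.

.fine_dt <- 1 / 60
.fine_centers <- seq(4 + .fine_dt / 2, 28 - .fine_dt / 2, by = .fine_dt)

#' Default parameters of the synthetic generator
#'
#' Ground-truth dynamics: `a_night + b_night * N_length` hours of nocturnal
#' rest (minus `c_night` per degree above the temperature threshold), and
#' `e_break + c_break * max(0, theta - theta_star)` hours of afternoon
#' break. Mixture shape: component weights `w` (wake, noon, evening,
#' bedtime), fixed widths, noon mode pinned at 12 h; the wake, evening and
#' bedtime centres are calibrated per day. `nu` splits the photoperiod
#' swing of T_night between a later waking (morning side) and an earlier
#' last call (night side). `conserved = TRUE` couples `c_night = c_break`
#' so the total daily resting time has zero temperature response.
#'
#' @param ... Overrides of any default.
#' @return Named list of generator parameters.
#' @export
synth_params <- function(...) {
  p <- list(
    a_night = 5.0,     # h, intercept of the T_night law
    b_night = 0.4,     # h of night rest per h of astronomical night
    c_night = 0.0,     # h lost per deg C above threshold (night side)
    e_break = 4.5,     # h, cold-regime afternoon break
    c_break = 0.05,    # h gained per deg C above threshold (break side)
    theta_star = 22,   # deg C
    conserved = FALSE,
    lambda = 0.9,      # calls per user per day
    w = c(F = 0.12, M = 0.42, N = 0.34, L = 0.12),
    t_M = 12.0, sigma_M = 2.0, sigma_N = 1.5, s_F = 1.2, s_L = 1.1,
    f0 = 8.6,          # h, baseline of the morning-side target t_F - s_F
    nu = 0.5,          # morning share of the photoperiod swing
    weekend_shift = 0  # h added to all centres on Fri/Sat/Sun
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  if (isTRUE(p$conserved)) p$c_night <- p$c_break
  p
}

#' Synthetic daily maximum temperatures
#'
#' `theta(d) = mean + amplitude * cos(2 * pi * (d - 202) / 365) + noise`,
#' peaking in late July (d = 202).
#'
#' @param city A [city_config()]. @param year Study year.
#' @param mean,amplitude Seasonal cosine parameters (deg C).
#' @param noise_sd Gaussian day-to-day noise (deg C). @param seed RNG seed.
#' @return A `temperature_series` data.frame: `d`, `date`, `theta`.
#' @export
generate_temperatures <- function(city, year = 2007, mean = 20,
                                  amplitude = 12, noise_sd = 2, seed = 1) {
  stopifnot(amplitude >= 0, noise_sd >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- 1:365
  theta <- mean + amplitude * cos(2 * pi * (d - 202) / 365) +
    rnorm(365, 0, noise_sd)
  out <- data.frame(d = d, date = as.Date(sprintf("%d-01-01", year)) + d - 1,
                    theta = theta)
  attr(out, "city") <- city
  class(out) <- c("temperature_series", "data.frame")
  out
}

#' Synthetic user cohort with planted filter violations
#'
#' Generates `n_users` subscribers. A fraction `1 - frac_invalid` passes
#' both geographic assignment rules and the 30--75 age filter (locations
#' within ~5 km of the city centre); the rest violate exactly one rule,
#' cycling through: both locations far from the centre, postal location far
#' from the MACT, and age out of range. The violation type per user is
#' recorded in the returned truth table.
#'
#' @param city A [city_config()]. @param n_users Cohort size.
#' @param frac_invalid Fraction with a planted violation. @param seed Seed.
#' @return list with `users` (data.frame `user_id`, `age`, `gender`,
#'   `postal_lat`, `postal_lon`, `mact_lat`, `mact_lon`) and `truth`
#'   (data.frame `user_id`, `valid`, `violation`).
#' @export
generate_users <- function(city, n_users, frac_invalid = 0, seed = 1) {
  stopifnot(n_users >= 0, frac_invalid >= 0, frac_invalid <= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km_lat <- 1 / 111.1949
  km_lon <- 1 / (111.1949 * cos(city$lat * pi / 180))
  empty <- data.frame(user_id = character(0), age = integer(0),
                      gender = character(0),
                      postal_lat = numeric(0), postal_lon = numeric(0),
                      mact_lat = numeric(0), mact_lon = numeric(0))
  if (n_users == 0)
    return(list(users = empty,
                truth = data.frame(user_id = character(0),
                                   valid = logical(0),
                                   violation = character(0))))
  n_bad <- round(n_users * frac_invalid)
  valid <- rep(TRUE, n_users)
  if (n_bad > 0) valid[sample.int(n_users, n_bad)] <- FALSE
  violation <- rep("none", n_users)
  violation[!valid] <- rep(c("far_center", "far_separation", "age_range"),
                           length.out = n_bad)

  loc_near <- function(n, r_km) {
    # uniform in a disc of radius r_km around the centre
    r <- r_km * sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
    cbind(lat = city$lat + r * sin(a) * km_lat,
          lon = city$lon + r * cos(a) * km_lon)
  }
  postal <- loc_near(n_users, 5)
  mact <- loc_near(n_users, 5)
  age <- sample(30:75, n_users, replace = TRUE)

  i <- violation == "far_center"   # both locations 20-25 km out
  if (any(i)) {
    far <- 20 + 5 * runif(sum(i)); a <- runif(sum(i), 0, 2 * pi)
    postal[i, ] <- cbind(city$lat + far * sin(a) * km_lat,
                         city$lon + far * cos(a) * km_lon)
    mact[i, ] <- cbind(postal[i, 1] + 1 * km_lat, postal[i, 2])
  }
  i <- violation == "far_separation"  # MACT near centre, postal 35-45 km off
  if (any(i)) {
    far <- 35 + 10 * runif(sum(i)); a <- runif(sum(i), 0, 2 * pi)
    postal[i, ] <- cbind(mact[i, 1] + far * sin(a) * km_lat,
                         mact[i, 2] + far * cos(a) * km_lon)
  }
  i <- violation == "age_range"
  if (any(i)) age[i] <- sample(c(18:29, 76:90), sum(i), replace = TRUE)

  users <- data.frame(
    user_id = sprintf("u%06d", seq_len(n_users)),
    age = age,
    gender = sample(c("F", "M"), n_users, replace = TRUE),
    postal_lat = postal[, 1], postal_lon = postal[, 2],
    mact_lat = mact[, 1], mact_lon = mact[, 2]
  )
  list(users = users,
       truth = data.frame(user_id = users$user_id, valid = valid,
                          violation = violation))
}

# --- population curves of one synthetic day ------------------------------

# Four-component density on the fine (1-minute) grid, truncated to [4, 28)
# and normalized; centres = c(mu_F, t_M, t_N, mu_L).
.mix_density <- function(centers, sds, w) {
  g <- w[1] * dnorm(.fine_centers, centers[1], sds[1]) +
       w[2] * dnorm(.fine_centers, centers[2], sds[2]) +
       w[3] * dnorm(.fine_centers, centers[3], sds[3]) +
       w[4] * dnorm(.fine_centers, centers[4], sds[4])
  g / (sum(g) * .fine_dt)
}

.agg_bins <- function(cellmass) {
  # 1-minute cells -> 5-minute bins
  colSums(matrix(cellmass, nrow = 5))
}

# Expected per-bin masses of P_all (full day), P_F (first morning call) and
# P_L (last night call) for one day's mixture, via the Poisson order
# statistic of a process with intensity lambda * g(t).
.pop_day_curves <- function(centers, sds, w, lambda) {
  cellmass <- .mix_density(centers, sds, w) * .fine_dt
  tt <- .fine_centers
  morning <- tt > 5 & tt < 16
  night <- tt > 17

  first_mass <- function(cm) {
    lam_cum <- lambda * (cumsum(cm) - cm / 2)
    m <- cm * exp(-lam_cum)
    m / sum(m)
  }
  last_mass <- function(cm) {
    lam_rev <- lambda * (rev(cumsum(rev(cm))) - cm / 2)
    m <- cm * exp(-lam_rev)
    m / sum(m)
  }
  list(
    full = .agg_bins(cellmass),
    first = .agg_bins(first_mass(cellmass[morning])),
    last = .agg_bins(last_mass(cellmass[night])),
    cellmass = cellmass
  )
}

# Estimator-side population values of one day: the morning-side statistic
# t_F - s_F, the night-side statistic t_L + s_L, and (optionally) T_break
# from the two-Gaussian fit -- all measured through the same binning and
# smoothing the pipeline applies.
.pop_day_stats <- function(centers, sds, w, lambda, smooth = TRUE,
                           with_break = FALSE) {
  cur <- .pop_day_curves(centers, sds, w, lambda)
  pf <- .profile_from_mass(cur$first, "morning", smooth)
  pl <- .profile_from_mass(cur$last, "night", smooth)
  out <- list(F_stat = pf$mean - pf$sd, L_stat = pl$mean + pl$sd,
              curves = cur)
  if (with_break) {
    fit <- fit_two_gaussians(.profile_from_mass(cur$full, "full", smooth))
    out$t_break <- t_break(fit)
    out$fit <- fit
  }
  out
}

# Calibrate one day's free centres (mu_F, mu_L, t_N) so the estimator's
# population values hit the targets. Two coordinate sweeps with a final
# night-side solve; each solve is monotone in its knob.
.calibrate_day <- function(target_F, target_L, target_break, p,
                           start = NULL, smooth = TRUE) {
  sds <- c(p$s_F, p$sigma_M, p$sigma_N, p$s_L)
  ctr <- if (is.null(start)) c(8.5, p$t_M, 20, 23.5) else start

  solve_mu_F <- function(ctr) {
    f <- function(m) {
      .pop_day_stats(c(m, ctr[2:4]), sds, p$w, p$lambda, smooth)$F_stat -
        target_F
    }
    uniroot(f, c(6.3, 13.5), tol = 1e-4)$root  # monotone branch
  }
  solve_mu_L <- function(ctr) {
    f <- function(m) {
      .pop_day_stats(c(ctr[1:3], m), sds, p$w, p$lambda, smooth)$L_stat -
        target_L
    }
    uniroot(f, c(19.5, 27.0), tol = 1e-4)$root  # monotone branch
  }
  solve_t_N <- function(ctr) {
    f <- function(tn) {
      .pop_day_stats(c(ctr[1:2], tn, ctr[4]), sds, p$w, p$lambda, smooth,
                     with_break = TRUE)$t_break - target_break
    }
    # bracket around the warm start, then polish
    lo <- max(17.6, ctr[3] - 1); hi <- min(25.5, ctr[3] + 1)
    flo <- f(lo); fhi <- f(hi)
    while (flo > 0 && lo > 17.6) { lo <- max(17.6, lo - 1); flo <- f(lo) }
    while (fhi < 0 && hi < 25.5) { hi <- min(25.5, hi + 1); fhi <- f(hi) }
    uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi, tol = 2e-3)$root
  }

  for (sweep in 1:2) {
    ctr[1] <- solve_mu_F(ctr)
    ctr[4] <- solve_mu_L(ctr)
    ctr[3] <- solve_t_N(ctr)
  }
  ctr[4] <- solve_mu_L(ctr)  # nail the night-side target last
  ctr
}

#' Synthetic call-detail records for one city-year
#'
#' Draws, for every user and logical day, a Poisson(`lambda`) number of
#' outgoing calls from the calibrated four-component daily intensity on the
#' extended axis `[4, 28)`, and emits a time-sorted call stream together
#' with the ground-truth channel: the per-day true resting durations and
#' the calibrated mixture geometry that realizes them.
#'
#' @param city A [city_config()]. @param users User data.frame (all listed
#'   users place calls; filters are exercised downstream).
#' @param year Study year. @param nights A [night_length_series()] for the
#'   city. @param temps A [generate_temperatures()] series.
#' @param params A [synth_params()] list. @param seed RNG seed.
#' @param days Day indices to simulate (default the full year).
#' @param smooth Calibrate against Savitzky-Golay-smoothed histograms
#'   (keep equal to the extraction setting).
#' @return list with `calls` (data.table `user_id`, `timestamp` ISO 8601
#'   with UTC offset, time-sorted) and `truth` (list: `params`, `city`,
#'   `daily` data.frame with `d`, `n_length`, `theta`, `t_night_true`,
#'   `t_break_true`, `mu_F`, `t_M`, `t_N`, `mu_L`, `target_F`,
#'   `target_L`).
#' @export
generate_calls <- function(city, users, year = 2007, nights, temps,
                           params = synth_params(), seed = 1,
                           days = 1:365, smooth = TRUE) {
  stopifnot(inherits(nights, "night_length_series"),
            all(days >= 1), all(days <= 365))
  p <- params
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n_len <- nights$n_length[match(1:365, nights$d)]
  theta <- temps$theta[match(1:365, temps$d)]
  n_ref <- mean(n_len)
  relu <- function(x) pmax(0, x)

  tn_true <- p$a_night + p$b_night * n_len - p$c_night * relu(theta - p$theta_star)
  tb_true <- p$e_break + p$c_break * relu(theta - p$theta_star)
  # morning-side target carries the nu-share of the photoperiod swing
  target_F <- p$f0 + p$nu * p$b_night * (n_len - n_ref)
  target_F_next <- c(target_F[-1], target_F[365])
  target_L <- 24 + target_F_next - tn_true

  days <- sort(unique(as.integer(days)))
  centers <- matrix(NA_real_, nrow = 365, ncol = 4,
                    dimnames = list(NULL, c("mu_F", "t_M", "t_N", "mu_L")))
  start <- NULL
  for (dd in days) {
    ctr <- .calibrate_day(target_F[dd], target_L[dd], tb_true[dd], p,
                          start = start, smooth = smooth)
    centers[dd, ] <- ctr
    start <- ctr
  }

  wd <- as.integer(weekday_labels(1:365, year))
  sds <- c(p$s_F, p$sigma_M, p$sigma_N, p$s_L)
  n_users <- nrow(users)
  date0 <- as.Date(sprintf("%d-01-01", year))

  chunks <- vector("list", length(days))
  for (k in seq_along(days)) {
    dd <- days[k]
    if (n_users == 0 || p$lambda == 0) break
    ctr <- centers[dd, ]
    if (p$weekend_shift != 0 && wd[dd] >= 5) ctr <- ctr + p$weekend_shift
    cellmass <- .mix_density(ctr, sds, p$w) * .fine_dt
    k_u <- rpois(n_users, p$lambda)
    n_d <- sum(k_u)
    if (n_d == 0) next
    cells <- sample.int(length(cellmass), n_d, replace = TRUE,
                        prob = cellmass)
    t_ext <- 4 + (cells - 1 + runif(n_d)) * .fine_dt
    chunks[[k]] <- data.table(user_id = rep(users$user_id, k_u),
                              d = dd, t = t_ext)
  }
  calls <- data.table::rbindlist(chunks[!vapply(chunks, is.null, logical(1))])
  if (nrow(calls)) {
    sec <- round((calls$t - 4) * 3600)
    date <- date0 + (calls$d - 1) + (sec >= 20 * 3600)
    clock <- (sec + 4 * 3600) %% 86400
    off <- sprintf("%+03d00", as.integer(round(city$utc_offset)))
    ts <- sprintf("%sT%02d:%02d:%02d%s", format(date, "%Y-%m-%d"),
                  clock %/% 3600, (clock %% 3600) %/% 60, clock %% 60, off)
    calls <- data.table(user_id = calls$user_id, timestamp = ts)[order(ts)]
  } else {
    calls <- data.table(user_id = character(0), timestamp = character(0))
  }

  daily <- data.frame(d = days, n_length = n_len[days], theta = theta[days],
                      t_night_true = tn_true[days],
                      t_break_true = tb_true[days],
                      mu_F = centers[days, 1], t_M = centers[days, 2],
                      t_N = centers[days, 3], mu_L = centers[days, 4],
                      target_F = target_F[days], target_L = target_L[days])
  list(calls = calls,
       truth = list(params = p, city = city$name, seed = seed, daily = daily))
}
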