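# Seasonal analyses: night-length regression, the implied seasonal swing,
# and the lagged cross-correlation between resting and night-length series.

#' Regress weekly resting duration on weekly night length
#'
#' Ordinary least squares of `T_night = beta * N_length + alpha` on paired
#' weekly aggregates, with the Pearson correlation and its two-sided
#' p-value computed from the same pairs. Pairs with a missing value are
#' dropped.
#'
#' @param t_weekly,n_weekly Paired numeric vectors (e.g. Mon--Thu means per
#'   week of T_night and N_length).
#' @return list with `beta`, `alpha`, `r`, `p`, `n`.
#' @export
regress_night_length <- function(t_weekly, n_weekly) {
  stopifnot(length(t_weekly) == length(n_weekly))
  ok <- is.finite(t_weekly) & is.finite(n_weekly)
  x <- n_weekly[ok]; y <- t_weekly[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0) stop("night-length regressor is constant; slope undefined")
  fit <- lm(y ~ x)
  ct <- cor.test(x, y)
  list(beta = unname(coef(fit)[2]), alpha = unname(coef(fit)[1]),
       r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Seasonal swing of the nocturnal resting period
#'
#' `delta_season = beta * (N_length(d = 356) - N_length(d = 172))`: the
#' regression-implied difference in resting duration between the winter and
#' summer solstices.
#'
#' @param beta Regression slope (hours of T_night per hour of night).
#' @param nights A [night_length_series()].
#' @return list with `hours` and `minutes`.
#' @export
delta_season <- function(beta, nights) {
  stopifnot(is.finite(beta), inherits(nights, "night_length_series"))
  dn <- nights$n_length[nights$d == 356] - nights$n_length[nights$d == 172]
  list(hours = beta * dn, minutes = 60 * beta * dn)
}

#' Normalized lagged cross-correlation of two day series
#'
#' For series X, Y of equal length n, computes
#' `rho(tau) = 1/(n - |tau|) * sum_i z_X(i) * z_Y(i + tau)` over the
#' overlapping indices, where the z-scores use the global means and
#' population standard deviations of each full series. Missing values are
#' dropped pairwise with the day index preserved (no re-compaction); the
#' overlap normalization then counts the valid pairs at that lag, which
#' equals `n - |tau|` for complete series. `best_lag` is the lag
#' maximizing `rho`, ties broken toward zero.
#'
#' @param x,y Numeric vectors of equal length (NA allowed).
#' @param tau_max Maximum |lag| in days; must be at most `length(x) / 2`.
#' @return A `cross_correlation`: list with `lags`, `rho`, `best_lag`.
#' @export
cross_correlation <- function(x, y, tau_max = 60) {
  n <- length(x)
  stopifnot(length(y) == n, tau_max <= n / 2)
  zscore <- function(v) {
    ok <- is.finite(v)
    m <- mean(v[ok])
    s <- sqrt(mean((v[ok] - m)^2))  # population sd, as in the overlap form
    if (!is.finite(s) || s == 0) stop("zero-variance input series")
    (v - m) / s
  }
  zx <- zscore(x); zy <- zscore(y)
  lags <- -tau_max:tau_max
  rho <- vapply(lags, function(tau) {
    i <- seq_len(n)
    j <- i + tau
    keep <- j >= 1 & j <= n
    prod <- zx[i[keep]] * zy[j[keep]]
    valid <- is.finite(prod)
    if (!any(valid)) return(NA_real_)
    sum(prod[valid]) / sum(valid)
  }, numeric(1))
  best <- lags[order(-rho, abs(lags))][1]
  structure(list(lags = lags, rho = rho, best_lag = best),
            class = "cross_correlation")
}

#' @export
print.cross_correlation <- function(x, ...) {
  cat(sprintf("<cross_correlation> lags %d..%d, best lag %d (rho = %.3f)\n",
              min(x$lags), max(x$lags), x$best_lag,
              x$rho[x$lags == x$best_lag]))
  invisible(x)
}

#' Pearson correlation between daily resting and night-length series
#'
#' All days of the week enter; pairs with missing values are dropped.
#'
#' @param t_night,n_length Paired daily series.
#' @return list with `r`, `p`, `n`.
#' @export
cor_night_length <- function(t_night, n_length) {
  ok <- is.finite(t_night) & is.finite(n_length)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  ct <- cor.test(n_length[ok], t_night[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
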