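# Temperature-threshold detection for the afternoon break: Shi-Malik
# spectral clustering of the (theta, T_break) scatter into a cold and a
# warm regime, the threshold estimate theta*, and regime-wise correlations.

# Shi-Malik normalized-cut bipartition: radial-kernel affinity on
# standardized coordinates, second eigenvector of the random-walk
# Laplacian, thresholded at the splitting point that minimizes the
# normalized cut (the original prescription; deterministic, and robust to
# the uneven within-branch spread of the embedding that throws off a
# k-means split).
.shi_malik_bipartition <- function(X, kernel_scale = 1, seed = 1) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  med <- median(D2[upper.tri(D2)])
  if (med <= 0) stop("degenerate point set: all points identical")
  sigma2 <- kernel_scale^2 * med
  W <- exp(-D2 / (2 * sigma2))
  diag(W) <- 0
  deg <- rowSums(W)
  Dis <- 1 / sqrt(deg)
  Lsym <- diag(n) - (Dis * W) %*% diag(Dis)  # I - D^-1/2 W D^-1/2
  eig <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  v <- Dis * eig$vectors[, n - 1]  # random-walk eigenvector, 2nd smallest

  ord <- order(v)
  Wo <- W[ord, ord]
  dego <- deg[ord]
  vol <- cumsum(dego)
  voltot <- vol[n]
  # assoc(A, A) for A = first k points in eigenvector order, incrementally
  assoc <- numeric(n)
  acc <- 0
  for (k in 2:n) {
    acc <- acc + 2 * sum(Wo[k, 1:(k - 1)])
    assoc[k] <- acc
  }
  cut <- vol - assoc
  ncut <- cut[1:(n - 1)] / vol[1:(n - 1)] +
    cut[1:(n - 1)] / (voltot - vol[1:(n - 1)])
  kbest <- which.min(ncut)
  cl <- integer(n)
  cl[ord] <- rep(1:2, c(kbest, n - kbest))
  cl
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# mean silhouette width for a 2-cluster labeling
.silhouette_mean <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  s <- vapply(seq_len(nrow(X)), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(D[i, own])
    b <- mean(D[i, labels != labels[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Split the temperature / afternoon-break scatter into two regimes
#'
#' Standardizes the `(theta, t_break)` coordinates to zero mean and unit
#' variance, builds a radial-kernel similarity graph (scale = median
#' pairwise distance times `kernel_scale`), and bipartitions it by
#' Shi-Malik normalized-cut spectral clustering. The cluster with the lower
#' mean temperature is labeled `"cold"`. A mean silhouette width below
#' `low_conf` raises the low-confidence flag; the default 0.4 separates a
#' forced split of one compact cloud (which silhouettes near 0.3) from
#' genuine two-regime structure (near 0.55 at pipeline effect sizes).
#'
#' @param theta Daily maximum temperatures (deg C).
#' @param t_break Afternoon break durations (hours), same length.
#' @param kernel_scale Multiplier on the median-distance kernel scale.
#' @param seed Seed for the k-means step of the spectral split.
#' @param low_conf Silhouette threshold for the low-confidence flag.
#' @return list with `labels` (factor cold/warm), `silhouette`,
#'   `low_confidence`.
#' @export
cluster_two_regimes <- function(theta, t_break, kernel_scale = 1, seed = 1,
                                low_conf = 0.4) {
  ok <- is.finite(theta) & is.finite(t_break)
  if (sum(ok) < 30) stop("need at least 30 complete (theta, t_break) points")
  zcol <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  X <- cbind(zcol(theta[ok]), zcol(t_break[ok]))
  if (all(X == 0)) stop("degenerate point set: all points identical")
  cl <- .shi_malik_bipartition(X, kernel_scale, seed)
  cold_id <- which.min(tapply(theta[ok], cl, mean))
  lab_ok <- factor(ifelse(cl == cold_id, "cold", "warm"),
                   levels = c("cold", "warm"))
  sil <- .silhouette_mean(X, cl)
  labels <- factor(rep(NA_character_, length(theta)),
                   levels = c("cold", "warm"))
  labels[ok] <- lab_ok
  list(labels = labels, silhouette = sil, low_confidence = sil < low_conf)
}

#' Threshold temperature between the cold and warm regimes
#'
#' Reads the threshold off the two spectral-clustering regimes. The default
#' `"intersect"` estimator uses the clusters to delimit two unambiguous
#' temperature zones -- clearly cold (below both the cold cluster's 95th
#' and the warm cluster's 5th temperature percentile) and clearly warm
#' (above both) -- then fits the flat cold level and the warm-side line on
#' *all* days inside each zone, and returns the temperature where the warm
#' line descends to the cold level. Two design points matter here: (i)
#' when the warm response is a continuous ramp, the normalized cut settles
#' where the ramp has risen appreciably, well above its onset, so label
#' quantiles alone over-estimate the threshold; and (ii) within the
#' interleaved mid-range, cluster membership is noise-selected (a mildly
#' warm day joins the warm cluster only when its break happens to be
#' high), so within-cluster regressions are selection-biased -- fitting on
#' all points of a cluster-delimited zone avoids both. If the warm-side
#' slope is not positive or the intersection leaves the observed
#' temperature range, the estimate falls back to the `"percentile"` rule:
#' the midpoint between the cold cluster's 95th and the warm cluster's 5th
#' temperature percentile (their median when the percentiles cross).
#' `"min_warm"` uses the minimum temperature of the warm cluster.
#'
#' @param theta Temperatures. @param labels cold/warm factor
#'   (from [cluster_two_regimes()]).
#' @param t_break Afternoon break durations; required for `"intersect"`.
#' @param method `"intersect"` (default), `"percentile"` or `"min_warm"`.
#' @return Threshold temperature theta* (deg C).
#' @export
threshold_temperature <- function(theta, labels, t_break = NULL,
                                  method = c("intersect", "percentile",
                                             "min_warm")) {
  method <- match.arg(method)
  ok <- !is.na(labels) & is.finite(theta)
  cold <- theta[ok & labels == "cold"]
  warm <- theta[ok & labels == "warm"]
  if (!length(cold) || !length(warm))
    stop("both regimes must be non-empty")
  if (method == "min_warm") return(min(warm))
  percentile_rule <- function() {
    hi_cold <- unname(quantile(cold, 0.95))
    lo_warm <- unname(quantile(warm, 0.05))
    if (hi_cold <= lo_warm) (hi_cold + lo_warm) / 2
    else median(c(hi_cold, lo_warm))
  }
  if (method == "percentile") return(percentile_rule())
  if (is.null(t_break))
    stop("t_break values are required for the intersect estimator")
  hi_cold <- unname(quantile(cold, 0.95))
  lo_warm <- unname(quantile(warm, 0.05))
  use <- ok & is.finite(t_break)
  iw <- use & theta >= max(hi_cold, lo_warm)  # clearly warm zone, all labels
  ic <- use & theta <= min(hi_cold, lo_warm)  # clearly cold zone, all labels
  if (sum(ic) < 5) ic <- use & labels == "cold"
  if (sum(iw) < 10 || sd(theta[iw]) == 0) return(percentile_rule())
  wfit <- coef(lm(t_break[iw] ~ theta[iw]))
  level_cold <- mean(t_break[ic])
  if (!is.finite(wfit[2]) || wfit[2] <= 0) return(percentile_rule())
  xstar <- unname((level_cold - wfit[1]) / wfit[2])
  if (xstar < min(theta[ok]) || xstar > max(theta[ok])) return(percentile_rule())
  xstar
}

#' Regime-wise correlation of the afternoon break with temperature
#'
#' Pearson correlations (with two-sided p-values) computed separately on
#' days with `theta < theta_star` and `theta >= theta_star`. A regime with
#' fewer than 3 points yields `NA` for that side.
#'
#' @param theta,t_break Paired daily values.
#' @param theta_star Threshold temperature.
#' @return list `r_below`, `p_below`, `n_below`, `r_above`, `p_above`,
#'   `n_above`.
#' @export
regime_correlations <- function(theta, t_break, theta_star) {
  ok <- is.finite(theta) & is.finite(t_break)
  side <- function(keep) {
    if (sum(keep) < 3)
      return(list(r = NA_real_, p = NA_real_, n = sum(keep)))
    ct <- cor.test(theta[keep], t_break[keep])
    list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
  }
  below <- side(ok & theta < theta_star)
  above <- side(ok & theta >= theta_star)
  list(r_below = below$r, p_below = below$p, n_below = below$n,
       r_above = above$r, p_above = above$p, n_above = above$n)
}

#' Simulate an afternoon-break / temperature scatter
#'
#' Direct scatter-level emulation of one city-year of `(theta, T_break)`
#' points: seasonal temperatures and a flat-then-linear break response
#' `T_break = e_break + c_break * max(0, theta - theta_star) + noise`.
#' Used for replicate studies of the regime statistics at effect sizes the
#' full pipeline produces, without paying for call-level simulation.
#'
#' @param n_days Number of days. @param theta_star Threshold (deg C).
#' @param e_break Cold-regime break duration (h). @param c_break Warm-side
#'   slope (h per deg C). @param temp_mean,temp_amplitude,temp_noise_sd
#'   Seasonal temperature model (deg C). @param break_noise_sd Estimation
#'   noise of daily T_break (h). @param seed RNG seed.
#' @return data.frame with `d`, `theta`, `t_break`.
#' @export
simulate_break_scatter <- function(n_days = 365, theta_star = 22,
                                   e_break = 4.5, c_break = 0.05,
                                   temp_mean = 20, temp_amplitude = 12,
                                   temp_noise_sd = 2, break_noise_sd = 0.1,
                                   seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- seq_len(n_days)
  theta <- temp_mean + temp_amplitude * cos(2 * pi * (d - 202) / 365) +
    rnorm(n_days, 0, temp_noise_sd)
  tb <- e_break + c_break * pmax(0, theta - theta_star) +
    rnorm(n_days, 0, break_noise_sd)
  data.frame(d = d, theta = theta, t_break = tb)
}
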