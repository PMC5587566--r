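# Daily activity profiles: P_all, P_F (first morning calls), P_L (last
# night calls), their moments, and the nocturnal resting statistic T_night.

#' Per-user first morning and last night call times
#'
#' For each user and logical day, reduces the call list to at most one
#' morning event (the first call in `[5, 16)`) and one night event (the
#' last call in `[17, 28)`). Calls in the afternoon `[16, 17)` and
#' nocturnal `[4, 5)` gaps belong to neither window.
#'
#' @param day_calls data.table from [logical_day()]: `user_id`, `d`, `t`.
#' @return list of two data.tables `first` and `last`, each with
#'   `user_id`, `d`, `t`.
#' @export
first_last_events <- function(day_calls) {
  dc <- as.data.table(day_calls)
  if (nrow(dc) == 0L) {
    empty <- data.table(user_id = character(0), d = integer(0),
                        t = numeric(0))
    return(list(first = empty, last = empty))
  }
  t <- NULL  # appease R CMD check
  morning <- dc[t >= 5 & t < 16, .(t = min(t)), by = c("user_id", "d")]
  night <- dc[t >= 17 & t < 28, .(t = max(t)), by = c("user_id", "d")]
  list(first = morning, last = night)
}

.hist_moments <- function(counts, centers) {
  s <- sum(counts)
  if (s <= 0) return(list(mean = NA_real_, sd = NA_real_))
  p <- counts / s
  m <- sum(p * centers)
  v <- sum(p * (centers - m)^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

#' Build a normalized daily activity profile
#'
#' Bins event times on the window's 5-minute grid, optionally smooths
#' (Savitzky-Golay 7, 4), normalizes to unit mass, and computes the mean
#' and standard deviation from the normalized histogram (bin centres
#' weighted by post-smoothing mass). Profiles with fewer than `min_events`
#' events are flagged invalid; a profile whose mass sits in a single bin is
#' flagged degenerate (sd = 0).
#'
#' @param t Event times on the extended axis.
#' @param window `"full"`, `"morning"` or `"night"`.
#' @param smooth Apply Savitzky-Golay smoothing before normalizing.
#' @param min_events Minimum event count for a valid profile (default 50).
#' @return An `activity_profile`: list with `window`, `density` (normalized
#'   mass per bin), `centers`, `mean`, `sd`, `n_events`, `valid`,
#'   `degenerate`, `histogram` (the [bin_and_smooth()] result).
#' @export
build_profile <- function(t, window = c("full", "morning", "night"),
                          smooth = TRUE, min_events = 50) {
  h <- bin_and_smooth(t, window, smooth = smooth)
  s <- sum(h$counts)
  dens <- if (s > 0) h$counts / s else h$counts
  mo <- .hist_moments(h$counts, h$centers)
  structure(
    list(window = h$window, density = dens, centers = h$centers,
         mean = mo$mean, sd = mo$sd, n_events = h$n_events,
         valid = h$n_events >= min_events,
         degenerate = isTRUE(mo$sd == 0),
         histogram = h),
    class = "activity_profile"
  )
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("<activity_profile> %s window: n=%d, mean=%.3f h, sd=%.3f h%s\n",
              x$window, x$n_events, x$mean, x$sd,
              if (!x$valid) " [invalid]" else ""))
  invisible(x)
}

# Build a profile directly from an expected (population) mass vector on a
# window's bin grid; used by the synthetic generator's calibration, which
# must measure gaps exactly as the estimator does.
.profile_from_mass <- function(mass, window, smooth = TRUE) {
  ws <- .window_spec(window)
  counts <- if (smooth) sg_smooth(mass) else mass
  mo <- .hist_moments(counts, ws$centers)
  structure(
    list(window = window, density = counts / sum(counts), centers = ws$centers,
         mean = mo$mean, sd = mo$sd, n_events = NA_integer_,
         valid = TRUE, degenerate = FALSE,
         histogram = list(counts = counts, raw_counts = mass,
                          centers = ws$centers, window = window,
                          smoothed = smooth)),
    class = "activity_profile"
  )
}

#' Nocturnal resting duration T_night
#'
#' `T_night(d) = 24 - (t_L + s_L) + (t_F - s_F)`, where `t_L`, `s_L` are
#' the mean and sd of day `d`'s last-call distribution on the extended
#' night axis (hours since midnight of day `d`, so values past midnight
#' exceed 24) and `t_F`, `s_F` those of day `d + 1`'s first-call
#' distribution. Either profile invalid gives `NA`.
#'
#' @param last_profile Night profile of day d ([build_profile()], night).
#' @param first_profile_next Morning profile of day d + 1.
#' @return Hours, in (0, 24), or `NA_real_`.
#' @export
t_night <- function(last_profile, first_profile_next) {
  if (is.null(last_profile) || is.null(first_profile_next)) return(NA_real_)
  if (!isTRUE(last_profile$valid) || !isTRUE(first_profile_next$valid))
    return(NA_real_)
  24 - (last_profile$mean + last_profile$sd) +
    (first_profile_next$mean - first_profile_next$sd)
}

#' Weekly weekday / weekend aggregates of a daily series
#'
#' Weeks start on Mondays (2007 conveniently begins on a Monday); for each
#' week the Monday--Thursday mean characterises typical weekdays and the
#' Friday--Sunday mean typical weekend days. Invalid or missing days are
#' skipped; a week with no valid day in a class yields `NA`.
#'
#' @param series data.frame with columns `d` and the value column.
#' @param value Name of the value column (default `"t_night"`).
#' @param year Study year.
#' @return data.frame with columns `week`, `mon_thu`, `fri_sun`.
#' @export
weekly_aggregates <- function(series, value = "t_night", year = 2007) {
  d <- series$d
  v <- series[[value]]
  wd <- as.integer(weekday_labels(d, year))
  week <- (d - 1) %/% 7 + 1
  agg <- function(keep) {
    out <- tapply(v[keep], week[keep], function(z) mean(z, na.rm = TRUE))
    out[is.nan(out)] <- NA_real_
    out
  }
  wk <- sort(unique(week))
  mt <- agg(wd <= 4)
  fs <- agg(wd >= 5)
  data.frame(week = wk,
             mon_thu = as.numeric(mt[as.character(wk)]),
             fri_sun = as.numeric(fs[as.character(wk)]))
}

#' Extract the daily resting series of one city
#'
#' The pipeline workhorse: from localized calls of one city (output of
#' [logical_day()]), builds per-day profiles of all calls, first morning
#' calls and last night calls, computes `T_night(d)` (pairing day d's night
#' with day d+1's morning) and `T_break(d)` (from the two-Gaussian fit of
#' the full-day profile), and labels weekdays. Day 365 has no following
#' morning and yields `NA` for `T_night`.
#'
#' @param day_calls data.table `user_id`, `d`, `t`.
#' @param year Study year.
#' @param smooth Savitzky-Golay smoothing of all histograms.
#' @param min_events Validity threshold per profile.
#' @param exclude_days Integer day indices to invalidate (e.g. the set
#'   reported by [detect_atypical_days()]).
#' @return A `resting_series` data.frame: `d`, `weekday`, `t_night`,
#'   `t_break`, `n_all`, `n_first`, `n_last`, `valid_night`, `valid_break`,
#'   `excluded`, per-profile moments (`all_mean`, `all_sd`, `first_mean`,
#'   `first_sd`, `last_mean`, `last_sd`), plus fitted mode parameters
#'   `fit_tM`, `fit_sM`, `fit_tN`, `fit_sN`, `fit_converged`.
#' @export
extract_resting_series <- function(day_calls, year = 2007, smooth = TRUE,
                                   min_events = 50, exclude_days = integer(0)) {
  dc <- as.data.table(day_calls)
  fl <- first_last_events(dc)
  lev <- 1:365
  all_by_d <- split(dc$t, factor(dc$d, levels = lev))
  first_by_d <- split(fl$first$t, factor(fl$first$d, levels = lev))
  last_by_d <- split(fl$last$t, factor(fl$last$d, levels = lev))
  profs <- vector("list", 365)
  for (dd in 1:365) {
    profs[[dd]] <- list(
      all = build_profile(all_by_d[[dd]], "full", smooth, min_events),
      first = build_profile(first_by_d[[dd]], "morning", smooth, min_events),
      last = build_profile(last_by_d[[dd]], "night", smooth, min_events)
    )
  }
  res <- data.frame(d = 1:365, weekday = weekday_labels(1:365, year),
                    t_night = NA_real_, t_break = NA_real_,
                    n_all = 0L, n_first = 0L, n_last = 0L,
                    valid_night = FALSE, valid_break = FALSE,
                    excluded = FALSE,
                    all_mean = NA_real_, all_sd = NA_real_,
                    first_mean = NA_real_, first_sd = NA_real_,
                    last_mean = NA_real_, last_sd = NA_real_,
                    fit_tM = NA_real_, fit_sM = NA_real_,
                    fit_tN = NA_real_, fit_sN = NA_real_,
                    fit_converged = FALSE)
  res$excluded <- res$d %in% exclude_days
  for (dd in 1:365) {
    p <- profs[[dd]]
    res$n_all[dd] <- p$all$n_events
    res$n_first[dd] <- p$first$n_events
    res$n_last[dd] <- p$last$n_events
    res$all_mean[dd] <- p$all$mean; res$all_sd[dd] <- p$all$sd
    res$first_mean[dd] <- p$first$mean; res$first_sd[dd] <- p$first$sd
    res$last_mean[dd] <- p$last$mean; res$last_sd[dd] <- p$last$sd
    if (dd < 365) {
      tn <- t_night(p$last, profs[[dd + 1]]$first)
      if (!res$excluded[dd] && !res$excluded[dd + 1] && !is.na(tn)) {
        res$t_night[dd] <- tn
        res$valid_night[dd] <- TRUE
      }
    }
    if (!res$excluded[dd] && p$all$valid) {
      fit <- fit_two_gaussians(p$all)
      res$fit_tM[dd] <- fit$tM; res$fit_sM[dd] <- fit$sM
      res$fit_tN[dd] <- fit$tN; res$fit_sN[dd] <- fit$sN
      res$fit_converged[dd] <- fit$converged
      tb <- t_break(fit)
      if (!is.na(tb)) {
        res$t_break[dd] <- tb
        res$valid_break[dd] <- TRUE
      }
    }
  }
  class(res) <- c("resting_series", "data.frame")
  res
}
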