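#' @importFrom data.table data.table as.data.table := .N fread rbindlist
#' @importFrom stats dnorm rnorm rpois runif sd mad median quantile lm coef
#'   cor cor.test complete.cases uniroot kmeans
NULL

# Window definitions on the extended daily axis [4, 28): a logical day runs
# from 04:00 of a calendar day to 03:59 of the next one, so that the
# overnight calling minimum never straddles a day boundary. Morning and
# night are each 11 h long; the [16,17) and [4,5) hours are the afternoon
# and nocturnal activity gaps, part of neither window.
.windows <- list(
  full    = c(4, 28),
  morning = c(5, 16),
  night   = c(17, 28)
)
.bin_width <- 5 / 60

.window_spec <- function(window = c("full", "morning", "night")) {
  window <- match.arg(window)
  w <- .windows[[window]]
  edges <- seq(w[1], w[2], by = .bin_width)
  list(name = window, lo = w[1], hi = w[2], edges = edges,
       centers = edges[-length(edges)] + .bin_width / 2)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km, vectorised.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000) / 1000
}

#' Assign users to a city by the two geographic closeness rules
#'
#' A user is accepted as living in the city when (i) at least one of their
#' two reference locations -- most-accessed cell tower (MACT) and postal-code
#' centre -- lies strictly within 15 km of the city centre, and (ii) the MACT
#' and postal locations lie strictly within 30 km of each other. Users with
#' either location missing are discarded.
#'
#' @param users data.frame with columns `user_id`, `mact_lat`, `mact_lon`,
#'   `postal_lat`, `postal_lon` (NA allowed; such users are discarded).
#' @param city A [city_config()] giving the city centre.
#' @param max_center_km Strict upper bound for rule (i); default 15.
#' @param max_sep_km Strict upper bound for rule (ii); default 30.
#'
#' @return The accepted subset of `users`, with attribute `drop_counts`
#'   (named integer vector: missing_location, center_rule, separation_rule).
#' @export
assign_users_to_city <- function(users, city, max_center_km = 15, max_sep_km = 30) {
  stopifnot(inherits(city, "city_config"))
  if (nrow(users) == 0L) {
    attr(users, "drop_counts") <- c(missing_location = 0L, center_rule = 0L,
                                    separation_rule = 0L)
    return(users)
  }
  has_loc <- complete.cases(users[, c("mact_lat", "mact_lon",
                                      "postal_lat", "postal_lon")])
  d_mact <- haversine_km(city$lat, city$lon, users$mact_lat, users$mact_lon)
  d_post <- haversine_km(city$lat, city$lon, users$postal_lat, users$postal_lon)
  d_sep <- haversine_km(users$mact_lat, users$mact_lon,
                        users$postal_lat, users$postal_lon)
  near_center <- pmin(d_mact, d_post) < max_center_km
  near_self <- d_sep < max_sep_km
  keep <- has_loc & near_center & near_self
  keep[is.na(keep)] <- FALSE
  out <- users[keep, , drop = FALSE]
  attr(out, "drop_counts") <- c(
    missing_location = sum(!has_loc),
    center_rule = sum(has_loc & !near_center, na.rm = TRUE),
    separation_rule = sum(has_loc & near_center & !near_self, na.rm = TRUE)
  )
  out
}

#' Filter users by age
#'
#' Keeps users whose age lies in the closed interval `[lo, hi]` (default
#' 30--75 years: younger subscribers call too erratically and older ones too
#' sparsely for population-level resting estimates).
#'
#' @param users data.frame with an `age` column.
#' @param lo,hi Closed age bounds.
#' @return Accepted subset with attribute `drop_counts` (named: age_rule).
#' @export
filter_age <- function(users, lo = 30, hi = 75) {
  keep <- !is.na(users$age) & users$age >= lo & users$age <= hi
  out <- users[keep, , drop = FALSE]
  attr(out, "drop_counts") <- c(age_rule = sum(!keep))
  out
}

#' Map call timestamps to logical days and extended-axis hours
#'
#' Converts absolute call instants to the city's local standard time and
#' assigns each call a logical day index `d` (1 = Jan 1) and a time `t` on
#' the extended axis `[4, 28)`: calls before 04:00 local belong to the
#' previous calendar day with `t = clock + 24`. Calls whose logical day
#' falls outside the study year are dropped and counted.
#'
#' @param calls data.frame with columns `user_id` and `timestamp`
#'   (POSIXct, or ISO 8601 strings with explicit UTC offset).
#' @param city A [city_config()] (its `utc_offset` defines local time).
#' @param year Study year.
#'
#' @return data.table with columns `user_id`, `d`, `t`, and attribute
#'   `dropped` (number of calls outside the year after the day shift).
#' @export
logical_day <- function(calls, city, year = 2007) {
  stopifnot(inherits(city, "city_config"))
  ts <- calls$timestamp
  if (!inherits(ts, "POSIXct"))
    ts <- as.POSIXct(ts, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamps in CDR input")
  # local standard time as seconds since the local year start
  local_sec <- as.numeric(ts) + city$utc_offset * 3600
  year_start <- as.numeric(as.POSIXct(sprintf("%d-01-01", year), tz = "UTC"))
  rel <- local_sec - year_start
  day0 <- floor(rel / 86400)            # calendar day offset from Jan 1
  clock <- (rel - day0 * 86400) / 3600  # local clock hours [0, 24)
  before4 <- clock < 4
  d <- as.integer(day0 + 1L - before4)
  t <- clock + 24 * before4
  ok <- d >= 1L & d <= 365L
  out <- data.table(user_id = calls$user_id[ok], d = d[ok], t = t[ok])
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Flag days with atypical total call volume
#'
#' Stand-in for holiday/festivity removal: a day is flagged when its total
#' call volume deviates from the median volume of the same weekday by more
#' than `k` (scaled) median absolute deviations. The flagged set is returned
#' for the caller to apply explicitly; nothing is removed here.
#'
#' @param volumes data.frame with columns `d` (day index) and `n` (total
#'   calls that day), one row per observed day.
#' @param year Study year (for weekday labels).
#' @param k MAD multiplier; `Inf` disables the filter. Default 5.
#' @return Integer vector of flagged day indices (possibly empty).
#' @export
detect_atypical_days <- function(volumes, year = 2007, k = 5) {
  if (nrow(volumes) < 56)
    stop("need at least 8 weeks of daily volumes")
  if (!is.finite(k)) return(integer(0))
  wd <- weekday_labels(volumes$d, year)
  flagged <- integer(0)
  for (w in unique(wd)) {
    i <- which(wd == w)
    m <- median(volumes$n[i])
    s <- mad(volumes$n[i])
    bad <- abs(volumes$n[i] - m) > k * s
    flagged <- c(flagged, volumes$d[i][bad])
  }
  sort(flagged)
}

#' Weekday labels for day-of-year indices
#'
#' @param d Day indices (1 = Jan 1).
#' @param year Calendar year.
#' @return Factor with levels Mon..Sun.
#' @export
weekday_labels <- function(d, year = 2007) {
  dates <- as.Date(sprintf("%d-01-01", year)) + (d - 1)
  lev <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  factor(lev[as.integer(strftime(dates, "%u"))], levels = lev)
}

# Central Savitzky-Golay smoothing row for window n, degree p, applied by
# convolution with mirror padding at the ends so the grid length is
# preserved.
.sg_coef <- function(n = 7, p = 4) {
  unclass(signal::sgolay(p = p, n = n))[(n + 1) / 2, ]
}

#' Savitzky-Golay smoothing with mirror padding
#'
#' Applies the Savitzky-Golay least-squares smoother (default 7 points,
#' degree 4) to a numeric series. Ends are handled by mirror padding so the
#' output has the same length; values driven below zero are clipped to zero
#' (the series are call counts).
#'
#' @param x Numeric vector.
#' @param n Window length (odd). @param p Polynomial degree.
#' @param clip Clip negative outputs to zero (default TRUE).
#' @return Smoothed vector, same length as `x`.
#' @export
sg_smooth <- function(x, n = 7, p = 4, clip = TRUE) {
  if (length(x) < n) return(x)
  m <- (n - 1) / 2
  xp <- c(x[(m + 1):2], x, x[(length(x) - 1):(length(x) - m)])
  co <- .sg_coef(n, p)
  out <- as.numeric(stats::filter(xp, co, sides = 2))[(m + 1):(m + length(x))]
  if (clip) out <- pmax(out, 0)
  out
}

#' Bin event times into the 5-minute grid of a daily window
#'
#' Left-closed, right-open 5-minute bins anchored at the window start. The
#' 11-hour morning and night windows yield exactly 132 bins; the full
#' extended day yields 288. Optionally Savitzky-Golay smoothed (7, 4).
#'
#' @param t Event times on the extended axis, all inside the window.
#' @param window `"full"`, `"morning"` or `"night"`.
#' @param smooth Apply Savitzky-Golay smoothing to the counts.
#' @return A `binned_histogram`: list with `counts`, `raw_counts`, `edges`,
#'   `centers`, `window`, `smoothed`, `n_events`.
#' @export
bin_and_smooth <- function(t, window = c("full", "morning", "night"),
                           smooth = TRUE) {
  ws <- .window_spec(match.arg(window))
  if (length(t) && (any(t < ws$lo) || any(t >= ws$hi)))
    stop("event times outside the ", ws$name, " window [",
         ws$lo, ", ", ws$hi, "); split events before binning")
  idx <- pmin(floor((t - ws$lo) / .bin_width) + 1L, length(ws$centers))
  raw <- tabulate(idx, nbins = length(ws$centers))
  counts <- if (smooth) sg_smooth(raw) else raw
  structure(
    list(counts = counts, raw_counts = raw, edges = ws$edges,
         centers = ws$centers, window = ws$name, smoothed = smooth,
         n_events = length(t)),
    class = "binned_histogram"
  )
}
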