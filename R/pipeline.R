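# Stage runners tying the modules into one reproducible file-level run:
# simulate -> extract -> analyze. Every output file starts with a comment
# header carrying the seed and a hash of the stage configuration, so reruns
# are verifiably identical and no stage reads another's internals except
# through these documented formats.

.config_hash <- function(cfg) {
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(js, tmp)
  unname(tools::md5sum(tmp))
}

.write_with_header <- function(x, path, header, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(x, con, sep = sep, row.names = FALSE, quote = FALSE)
}

.read_skip_header <- function(path, sep = "\t") {
  utils::read.delim(path, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
}

.stage_header <- function(stage, seed, hash) {
  sprintf("# restcdr %s seed=%d config=%s", stage, seed, hash)
}

#' Simulate a synthetic city and write its input files
#'
#' Runs the synthetic generator for one city-year and writes the stage's
#' file set under `dir`: `cities.json`, `users.csv`, `cdr.csv` (time-sorted
#' ISO 8601 timestamps), `temperatures.csv` (`date`, `tmax_c`) and
#' `truth.json` (the ground-truth channel). Deterministic under `seed`.
#'
#' @param dir Output directory (created if needed).
#' @param city A [city_config()].
#' @param n_users Cohort size. @param frac_invalid Planted-violation share.
#' @param year Study year. @param seed Master seed; stage sub-seeds are
#'   derived from it. @param params A [synth_params()] list.
#' @param temp_mean,temp_amplitude,temp_noise_sd Temperature model (deg C).
#' @param days Day indices to simulate.
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
run_simulate <- function(dir, city = city_config("synthville", 40, 0, 1, 6e5),
                         n_users = 2000, frac_invalid = 0, year = 2007,
                         seed = 1, params = synth_params(),
                         temp_mean = 20, temp_amplitude = 12,
                         temp_noise_sd = 2, days = 1:365) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(stage = "simulate", city = unclass(city), n_users = n_users,
              frac_invalid = frac_invalid, year = year, seed = seed,
              params = params, temp = c(temp_mean, temp_amplitude,
                                        temp_noise_sd))
  hash <- .config_hash(cfg)
  hdr <- .stage_header("simulate", seed, hash)

  nights <- night_length_series(city, year)
  temps <- generate_temperatures(city, year, temp_mean, temp_amplitude,
                                 temp_noise_sd, seed = seed + 1000L)
  cohort <- generate_users(city, n_users, frac_invalid, seed = seed + 2000L)
  sim <- generate_calls(city, cohort$users, year, nights, temps,
                        params = params, seed = seed, days = days)

  writeLines(jsonlite::toJSON(list(unclass(city)), auto_unbox = TRUE,
                              digits = NA),
             file.path(dir, "cities.json"))
  .write_with_header(cohort$users, file.path(dir, "users.csv"), hdr, sep = ",")
  .write_with_header(sim$calls, file.path(dir, "cdr.csv"), hdr, sep = ",")
  .write_with_header(
    data.frame(date = format(temps$date, "%Y-%m-%d"),
               tmax_c = temps$theta),
    file.path(dir, "temperatures.csv"), hdr, sep = ","
  )
  truth <- sim$truth
  truth$user_truth <- cohort$truth
  truth$config_hash <- hash
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"),
             file.path(dir, "truth.json"))
  invisible(list(dir = dir, city = city, nights = nights, temps = temps,
                 users = cohort$users, user_truth = cohort$truth,
                 calls = sim$calls, truth = sim$truth, hash = hash))
}

#' Extract resting series from a directory of call records
#'
#' Chains the user filters, logical-day assignment, atypical-day detection
#' and per-day profile construction for every city in `cities.json`, and
#' writes `resting_series.tsv`, `profiles.tsv`, `excluded_days.tsv` and
#' `filter_log.json` (per-rule drop counters; the audit trail for cohort
#' attrition) under `dir`.
#'
#' @param dir Directory holding `cities.json`, `users.csv`, `cdr.csv`.
#' @param year Study year. @param seed Seed recorded in headers (extraction
#'   itself is deterministic).
#' @param smooth Savitzky-Golay smoothing. @param min_events Profile
#'   validity threshold. @param atypical_k MAD multiplier for the volume
#'   outlier rule (`Inf` disables). @param apply_atypical Invalidate the
#'   flagged days (they are always reported).
#' @param max_center_km,max_sep_km,age_lo,age_hi Filter thresholds.
#' @return Invisibly, a list city -> `resting_series`, with the filter log
#'   as attribute `filter_log`.
#' @export
run_extract <- function(dir, year = 2007, seed = 1, smooth = TRUE,
                        min_events = 50, atypical_k = 5,
                        apply_atypical = TRUE, max_center_km = 15,
                        max_sep_km = 30, age_lo = 30, age_hi = 75) {
  cities <- jsonlite::fromJSON(file.path(dir, "cities.json"),
                               simplifyDataFrame = FALSE)
  users <- .read_skip_header(file.path(dir, "users.csv"), sep = ",")
  calls <- data.table::fread(file.path(dir, "cdr.csv"), skip = "user_id",
                             colClasses = list(character = c("user_id",
                                                             "timestamp")))
  cfg <- list(stage = "extract", year = year, smooth = smooth,
              min_events = min_events, atypical_k = atypical_k,
              apply_atypical = apply_atypical,
              thresholds = c(max_center_km, max_sep_km, age_lo, age_hi),
              seed = seed)
  hash <- .config_hash(cfg)
  hdr <- .stage_header("extract", seed, hash)

  out <- list()
  log <- list()
  prof_rows <- list()
  excl_rows <- list()
  for (cd in cities) {
    city <- city_config(cd$name, cd$lat, cd$lon, cd$utc_offset, cd$population)
    geo <- assign_users_to_city(users, city, max_center_km, max_sep_km)
    aged <- filter_age(geo, age_lo, age_hi)
    drops <- c(attr(geo, "drop_counts"), attr(aged, "drop_counts"))
    keep <- calls$user_id %in% aged$user_id
    lc <- logical_day(calls[keep], city, year)
    drops <- c(drops, calls_outside_year = attr(lc, "dropped"),
               calls_other_city_users = sum(!keep))
    vols <- as.data.frame(lc[, .N, by = "d"])
    names(vols) <- c("d", "n")
    excluded <- if (nrow(vols) >= 56)
      detect_atypical_days(vols, year, atypical_k) else integer(0)
    rs <- extract_resting_series(
      lc, year, smooth, min_events,
      exclude_days = if (apply_atypical) excluded else integer(0)
    )
    out[[city$name]] <- rs
    log[[city$name]] <- as.list(drops)
    if (length(excluded))
      excl_rows[[city$name]] <- data.frame(city = city$name, d = excluded)
    long <- rbind(
      data.frame(city = city$name, d = rs$d, kind = "all",
                 mean = rs$all_mean, sd = rs$all_sd, n = rs$n_all),
      data.frame(city = city$name, d = rs$d, kind = "first",
                 mean = rs$first_mean, sd = rs$first_sd, n = rs$n_first),
      data.frame(city = city$name, d = rs$d, kind = "last",
                 mean = rs$last_mean, sd = rs$last_sd, n = rs$n_last)
    )
    prof_rows[[city$name]] <- long
    message(sprintf(
      "extract [%s]: %d/%d users kept, %d calls, %d valid nights, %d atypical days",
      city$name, nrow(aged), nrow(users), nrow(lc), sum(rs$valid_night),
      length(excluded)))
  }

  series <- do.call(rbind, lapply(names(out), function(nm)
    cbind(city = nm, out[[nm]])))
  .write_with_header(series, file.path(dir, "resting_series.tsv"), hdr)
  .write_with_header(do.call(rbind, prof_rows),
                     file.path(dir, "profiles.tsv"), hdr)
  excl <- if (length(excl_rows)) do.call(rbind, excl_rows)
          else data.frame(city = character(0), d = integer(0))
  .write_with_header(excl, file.path(dir, "excluded_days.tsv"), hdr)
  writeLines(jsonlite::toJSON(list(seed = seed, config_hash = hash,
                                   drops = log),
                              auto_unbox = TRUE, digits = NA),
             file.path(dir, "filter_log.json"))
  attr(out, "filter_log") <- log
  invisible(out)
}

#' Analyze extracted resting series
#'
#' For every city: weekly night-length regression (weekday and weekend
#' aggregates), the implied seasonal swing, daily Pearson correlation,
#' lagged cross-correlation of the z-scored daily T_night and N_length
#' series, and the temperature-threshold analysis of T_break (spectral
#' two-regime clustering, threshold estimate, regime correlations). Writes
#' `regression.tsv`, `crosscorr.tsv`, `thermal.tsv` and `summary.json`
#' under `dir`; a city whose series is unusable is reported and skipped.
#'
#' @param dir Directory holding the extract outputs plus `cities.json` and
#'   `temperatures.csv`.
#' @param year Study year. @param seed Seed for the clustering k-means.
#' @param tau_max Maximum cross-correlation lag (days).
#' @param kernel_scale Affinity-scale multiplier for the clustering.
#' @return Invisibly, the per-city summary list.
#' @export
run_analyze <- function(dir, year = 2007, seed = 1, tau_max = 60,
                        kernel_scale = 1) {
  cities <- jsonlite::fromJSON(file.path(dir, "cities.json"),
                               simplifyDataFrame = FALSE)
  series <- .read_skip_header(file.path(dir, "resting_series.tsv"))
  temps <- .read_skip_header(file.path(dir, "temperatures.csv"), sep = ",")
  temps$d <- as.integer(strftime(as.Date(temps$date), "%j"))
  cfg <- list(stage = "analyze", year = year, seed = seed,
              tau_max = tau_max, kernel_scale = kernel_scale)
  hash <- .config_hash(cfg)
  hdr <- .stage_header("analyze", seed, hash)

  summary <- list()
  reg_rows <- list(); xc_rows <- list(); th_rows <- list()
  for (cd in cities) {
    nm <- cd$name
    rs <- series[series$city == nm, ]
    if (!nrow(rs) || sum(rs$valid_night, na.rm = TRUE) < 30) {
      message("analyze [", nm, "]: too few valid days, skipped")
      next
    }
    city <- city_config(nm, cd$lat, cd$lon, cd$utc_offset, cd$population)
    nights <- night_length_series(city, year)

    rs <- rs[order(rs$d), ]
    tn <- ifelse(rs$valid_night, rs$t_night, NA_real_)
    tb <- ifelse(rs$valid_break, rs$t_break, NA_real_)
    nl <- nights$n_length

    wk_t <- weekly_aggregates(data.frame(d = rs$d, v = tn), "v", year)
    wk_n <- weekly_aggregates(data.frame(d = nights$d, v = nl), "v", year)
    res_city <- list()
    for (cls in c("mon_thu", "fri_sun")) {
      reg <- regress_night_length(wk_t[[cls]], wk_n[[cls]])
      ds <- delta_season(reg$beta, nights)
      reg_rows[[paste(nm, cls)]] <- data.frame(
        city = nm, day_class = cls, beta = reg$beta, alpha = reg$alpha,
        r = reg$r, p = reg$p, n_weeks = reg$n,
        delta_season_h = ds$hours, delta_season_min = ds$minutes)
      res_city[[cls]] <- list(beta = reg$beta, alpha = reg$alpha,
                              r = reg$r, p = reg$p,
                              delta_season_min = ds$minutes)
    }

    xc <- cross_correlation(tn, nl, tau_max)
    xc_rows[[nm]] <- data.frame(city = nm, tau = xc$lags, rho = xc$rho)
    daily_cor <- cor_night_length(tn, nl)

    th <- temps$theta
    if (is.null(th)) th <- temps$tmax_c
    theta <- th[match(rs$d, temps$d)]
    thermal <- tryCatch({
      cl <- cluster_two_regimes(theta, tb, kernel_scale, seed)
      tstar <- threshold_temperature(theta, cl$labels, tb)
      rc <- regime_correlations(theta, tb, tstar)
      th_rows[[nm]] <- data.frame(
        city = nm, theta_star = tstar,
        r_below = rc$r_below, p_below = rc$p_below,
        r_above = rc$r_above, p_above = rc$p_above,
        n_cold = sum(cl$labels == "cold", na.rm = TRUE),
        n_warm = sum(cl$labels == "warm", na.rm = TRUE),
        silhouette = cl$silhouette)
      c(list(theta_star = tstar, silhouette = cl$silhouette,
             low_confidence = cl$low_confidence), rc)
    }, error = function(e) {
      message("analyze [", nm, "]: thermal analysis failed: ",
              conditionMessage(e))
      NULL
    })

    summary[[nm]] <- list(
      weekday = res_city$mon_thu, weekend = res_city$fri_sun,
      daily_r = daily_cor$r, daily_p = daily_cor$p,
      best_lag = xc$best_lag, thermal = thermal)
    message(sprintf(
      "analyze [%s]: beta=%.3f, delta_season=%.0f min, best lag=%d%s",
      nm, res_city$mon_thu$beta, res_city$mon_thu$delta_season_min,
      xc$best_lag,
      if (!is.null(thermal)) sprintf(", theta*=%.1f C", thermal$theta_star)
      else ""))
  }

  .write_with_header(do.call(rbind, reg_rows),
                     file.path(dir, "regression.tsv"), hdr)
  .write_with_header(do.call(rbind, xc_rows),
                     file.path(dir, "crosscorr.tsv"), hdr)
  th_df <- if (length(th_rows)) do.call(rbind, th_rows)
           else data.frame(city = character(0))
  .write_with_header(th_df, file.path(dir, "thermal.tsv"), hdr)
  writeLines(jsonlite::toJSON(list(seed = seed, config_hash = hash,
                                   cities = summary),
                              auto_unbox = TRUE, digits = NA),
             file.path(dir, "summary.json"))
  invisible(summary)
}
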