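# Shared fixtures and independent oracles used across the suite.

# Mid-latitude reference cities (longitude 0, UTC, synthetic registry).
city40 <- city_config("band40", lat = 40, lon = 0, utc_offset = 0,
                      population = 6e5)
city37 <- city_config("band37", lat = 37, lon = 0, utc_offset = 0,
                      population = 4e5)
city42 <- city_config("band42", lat = 42.5, lon = 0, utc_offset = 0,
                      population = 3e5)

# Brute-force double-loop cross-correlation: global means, population SDs,
# overlap-only summation with 1/(n - |tau|); written independently of the
# package implementation.
xcorr_bruteforce <- function(x, y, tau_max) {
  n <- length(x)
  zx <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  zy <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  sapply(-tau_max:tau_max, function(tau) {
    s <- 0
    for (i in 1:n) {
      j <- i + tau
      if (j >= 1 && j <= n) s <- s + zx[i] * zy[j]
    }
    s / (n - abs(tau))
  })
}

# Degree-based coordinate offsets corresponding to a distance in km along
# a meridian (1 deg latitude = 111.1949 km on the R = 6371 km sphere).
km_north <- function(km) km / 111.1949

# One user row at given offsets (km north of the city centre).
user_at <- function(id, city, mact_km, postal_km, age = 40) {
  data.frame(user_id = id, age = age, gender = "F",
             postal_lat = city$lat + km_north(postal_km),
             postal_lon = city$lon,
             mact_lat = city$lat + km_north(mact_km),
             mact_lon = city$lon)
}

# A small simulated run shared by pipeline tests: 250 users, 9 weeks.
tiny_run_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "restcdr-tiny-run")
      if (!file.exists(file.path(dir, "resting_series.tsv"))) {
        suppressMessages({
          run_simulate(dir, n_users = 250, seed = 7, days = 1:63)
          run_extract(dir)
        })
      }
    }
    dir
  }
})
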