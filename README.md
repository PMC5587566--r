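# restcdr

Resting-period dynamics of urban populations from mobile-phone call
records.

## What it does

When you aggregate the outgoing calls of a whole city, the daily calling
rate is bimodal: a noon peak, an evening peak, an afternoon dip around
4-5 pm and near-silence around 4-5 am. `restcdr` reads those two
low-activity windows as the population's resting periods and measures
them for every day of a year:

* **Nocturnal rest** — each user contributes their first call of the
  morning window (05:00-15:59) and last call of the night window
  (17:00-03:59, on an extended 4-28 h axis). With (t̄_F, σ_F) and
  (t̄_L, σ_L) the mean and SD of those two distributions,

      T_night(d) = 24 − (t̄_L(d) + σ_L) + (t̄_F(d+1) − σ_F)

* **Afternoon rest** — the full-day call distribution is fitted with a
  two-Gaussian superposition (noon mode t̄_M ± σ_M, evening mode
  t̄_N ± σ_N) and

      T_break(d) = (t̄_N − σ_N) − (t̄_M + σ_M)

The package then quantifies what drives the seasonality of the two:

* weekly regression `T̄_night = β·N̄_length + α` against the astronomical
  night length (NOAA solar geometry), with the implied solstice swing
  `δ_season = β·[N_length(d=356) − N_length(d=172)]`;
* the lagged cross-correlation ρ(τ) between the daily T_night and
  N_length series (overlap-normalized, z-scored);
* a temperature threshold θ\* for the afternoon break, from Shi–Malik
  spectral clustering of the (θ, T_break) scatter into a cold and a warm
  regime, with Pearson correlations per regime.

Population-scale call records are proprietary, so the package ships a
calibrated synthetic generator as a first-class module: it plants known
resting dynamics (a photoperiod law for T_night, a temperature-threshold
law for T_break) in a four-component daily calling intensity and emits
CDR/user/temperature files plus the ground truth, so the whole pipeline
is testable end to end. See the methods vignette
(`vignettes/resting-periods.Rmd`) for the model, the calibration and the
design decisions.

## Worked example

The analysis workflow is four thin scripts over the package functions:

```sh
Rscript analysis/01_simulate.R   # synthetic city -> results/run/
Rscript analysis/02_extract.R    # filters, profiles, T_night/T_break
Rscript analysis/03_analyze.R    # regression, delta_season, lag, theta*
Rscript analysis/04_report.R     # recovery vs truth + figures
```

A run with the default study conditions (one 40°N city, 2000 users, 365
days, 20% of users carrying planted filter violations) prints:

```
wrote results/run: 656200 calls from 2000 users, 365 simulated days
planted dynamics: T_night = 5.0 + 0.40 N_length; T_break = 4.5 + 0.05 relu(theta - 22)
extract [synthville]: 1600/2000 users kept, 524642 calls, 364 valid nights, 0 atypical days
synthville: beta = 0.394 h/h (r = 0.99), delta_season = 134 min (weekday) / 139 min (weekend)
   best cross-correlation lag = 0 d; theta* = 21.8 C (r_below = -0.09, r_above = 0.69)
t_night_rmse_min = 9.43; t_break_rmse_min = 9.91; beta_true = 0.40; theta_star_true = 22.00; theta_star_est = 21.84
```

Reading: the geographic and age filters removed exactly the planted 400
violators; the recovered night-length slope β̂ = 0.394 h/h matches the
planted 0.4 (so a ~5.6 h longer winter night buys ~134 extra minutes of
nocturnal rest over the season); the T_night and N_length series are in
phase (best lag 0); and the detected temperature threshold 21.8 °C
recovers the planted 22 °C, with the afternoon break uncorrelated with
temperature below it (r ≈ −0.09) and strongly correlated above it
(r ≈ 0.69). Daily estimates track the planted truth to ~9-10 minutes
RMSE, which is the sampling noise floor at 0.9 calls/user/day.

Programmatic use of the same machinery:

```r
library(restcdr)
city   <- city_config("synthville", lat = 40, lon = 0, utc_offset = 1,
                      population = 6e5)
nights <- night_length_series(city, 2007)
nights$d[which.max(nights$n_length)]   # 356, the winter solstice
sim <- run_simulate(tempfile(), city = city, n_users = 2000, seed = 1)
rs  <- run_extract(sim$dir)$synthville
head(rs[rs$valid_night, c("d", "weekday", "t_night", "t_break")])
```

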