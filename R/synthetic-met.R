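#' Season configuration for a synthetic campaign
#'
#' Defines the measurement window and site-level climate shape used by the
#' meteorology and soil generators. Defaults emulate a ~90-day high-Arctic
#' growing season (late May to end of August).
#'
#' @param start_doy,end_doy First and last day-of-year of the campaign
#'   (defaults 150 and 243).
#' @param year Calendar year used to build timestamps (default 2021).
#' @param utc_offset Hours offset of local standard time from UTC, stored
#'   for provenance only; all clock-hour rules operate on local time.
#' @param t_mean_peak Seasonal peak of daily-mean air temperature, degC.
#' @param t_diel_amp Diel half-amplitude of air temperature, degC.
#' @param par_max Clear-sky midsummer PAR maximum, umol m^-2 s^-1.
#' @param rain_day_prob Probability that a given day is rainy.
#'
#' @return A list of class `season_config`.
#' @export
season_config <- function(start_doy = 150, end_doy = 243, year = 2021,
                          utc_offset = -7, t_mean_peak = 14,
                          t_diel_amp = 4.5, par_max = 1150,
                          rain_day_prob = 0.25) {
  if (end_doy < start_doy) {
    stop("season must span at least one day", call. = FALSE)
  }
  structure(
    list(start_doy = start_doy, end_doy = end_doy, year = year,
         utc_offset = utc_offset, t_mean_peak = t_mean_peak,
         t_diel_amp = t_diel_amp, par_max = par_max,
         rain_day_prob = rain_day_prob),
    class = "season_config"
  )
}

# deterministic seed-splitting: every generator component draws from its
# own stream derived from the one top-level seed
split_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + 1013 * offset) %% 2147483647
}

ar1 <- function(n, phi, sd) {
  as.numeric(stats::filter(stats::rnorm(n, 0, sd), phi, method = "recursive"))
}

# circular hour distance, 24-h wrap
hour_dist <- function(h, mu) {
  d <- abs(h - mu)
  pmin(d, 24 - d)
}

hour_bump <- function(h, mu, sigma) {
  exp(-hour_dist(h, mu)^2 / (2 * sigma^2))
}

#' Simulate hourly meteorology and soil state for one season
#'
#' Generates the hourly driver series a chamber campaign needs:
#' meteorology (friction velocity, wind speed at 7 m, PAR, air
#' temperature, rain, air pressure) and soil state (temperature and
#' volumetric water content at the surface and at 10/20/30 cm, O2,
#' water-filled pore space, thaw depth) for each of the three vegetation
#' types. Built-in behaviour the downstream stages rely on:
#'
#' * PAR follows a high-latitude photoperiod: despite 24-h daylight in
#'   midsummer, PAR stays below 100 umol m^-2 s^-1 between 23:00 and
#'   06:00.
#' * Night-time calm episodes occur (low u* together with low wind), so
#'   the turbulence filter is exercised.
#' * Soil moisture dries down between rain events and rewets after rain;
#'   tussock profiles are wetter at depth than lichen or shrub.
#'
#' @param season A [season_config()].
#' @param seed Integer seed; identical seeds give identical series.
#'
#' @return A list with elements `met` (hourly tibble: `time`, `doy`,
#'   `hour`, `u_star`, `wind_speed`, `par`, `t_air`, `rain`,
#'   `pressure_air`) and `soil` (hourly tibble per vegetation type:
#'   `vegetation`, `time`, `t_soil_surface`, `t_soil_10`, `t_soil_20`,
#'   `t_soil_30`, `vwc_surface`, `vwc_10`, `vwc_20`, `vwc_30`,
#'   `wfps_surface` ... `wfps_30`, `o2`, `thaw_depth`, `bd`, `pd`).
#' @export
simulate_met <- function(season = season_config(), seed = 1) {
  stopifnot(inherits(season, "season_config"))
  days <- seq(season$start_doy, season$end_doy)
  n_days <- length(days)
  doy <- rep(days, each = 24)
  hour <- rep(0:23, times = n_days)
  n <- length(doy)
  time <- as.POSIXct(sprintf("%d-01-01 00:00:00", season$year), tz = "UTC") +
    (doy - 1) * 86400 + hour * 3600

  set.seed(split_seed(seed, 1))
  # air temperature: seasonal arc + diel cycle + synoptic AR(1) anomaly
  t_seas <- (season$t_mean_peak - 8) +
    8 * sin(pi * (doy - 140) / 105)
  syn <- ar1(n, 0.97, 0.45)
  t_air <- t_seas + season$t_diel_amp * cos(2 * pi * (hour - 14) / 24) + syn

  # PAR: clear-sky envelope peaking at 13:30 local, seasonal decline,
  # multiplicative cloudiness
  par_env <- season$par_max * (1 - 0.35 * abs(doy - 172) / 70)
  cloud <- 0.45 + 0.55 * stats::plogis(ar1(n, 0.9, 0.6))
  par <- par_env * hour_bump(hour, 13.5, 3.2) * cloud
  par[par < 0] <- 0

  # turbulence: lognormal u* suppressed at night, wind tied to u*
  night_factor <- ifelse(hour >= 22 | hour < 7, 0.45, 1)
  u_star <- 0.25 * night_factor * exp(stats::rnorm(n, 0, 0.45))
  wind_speed <- pmax(0.1, u_star * 7 + 0.5 + stats::rnorm(n, 0, 0.4))

  # rain: rainy days, showers within them
  rainy_day <- stats::runif(n_days) < season$rain_day_prob
  shower <- stats::runif(n) < 0.30
  rain <- ifelse(rep(rainy_day, each = 24) & shower,
                 stats::rgamma(n, shape = 1.3, scale = 1.1), 0)

  pressure_air <- 101.3 + ar1(n, 0.98, 0.05)

  met <- tibble::tibble(time = time, doy = doy, hour = hour,
                        u_star = u_star, wind_speed = wind_speed,
                        par = par, t_air = t_air, rain = rain,
                        pressure_air = pressure_air)

  soil <- dplyr::bind_rows(lapply(
    c("lichen", "shrub", "tussock"),
    function(v) simulate_soil_profile(v, met, seed)
  ))
  list(met = met, soil = soil)
}

# exponential smoothing (discrete first-order heat transfer)
smooth_rec <- function(x, alpha) {
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = x[1]))
}

# soil moisture bucket: dry-down towards vwc_min, rewetting from rain
vwc_bucket <- function(rain, vwc0, vwc_min, vwc_max, k_dry, infil) {
  n <- length(rain)
  v <- numeric(n)
  v[1] <- vwc0
  for (i in 2:n) {
    v[i] <- v[i - 1] - k_dry * (v[i - 1] - vwc_min) + infil * rain[i]
    if (v[i] > vwc_max) v[i] <- vwc_max
  }
  v
}

simulate_soil_profile <- function(vegetation, met, seed) {
  set.seed(split_seed(seed, 2 + match(vegetation,
                                      c("lichen", "shrub", "tussock"))))
  n <- nrow(met)
  bd <- 1.0
  pd <- 2.65
  porosity <- 1 - bd / pd

  t_surface <- smooth_rec(met$t_air, 0.25) - 1 +
    stats::rnorm(n, 0, 0.6)                  # microsite/sensor variability
  t_10 <- smooth_rec(met$t_air, 0.06) - 2.5
  t_20 <- smooth_rec(met$t_air, 0.02) - 4
  t_30 <- smooth_rec(met$t_air, 0.01) - 5.5

  # wetness regimes per vegetation type (surface, 30 cm)
  wet <- switch(vegetation,
    lichen  = list(min0 = 0.12, start0 = 0.18, max0 = 0.28,
                   min30 = 0.24, start30 = 0.28, max30 = 0.40),
    shrub   = list(min0 = 0.06, start0 = 0.11, max0 = 0.22,
                   min30 = 0.18, start30 = 0.23, max30 = 0.35),
    tussock = list(min0 = 0.25, start0 = 0.30, max0 = 0.40,
                   min30 = 0.36, start30 = 0.40, max30 = 0.56)
  )
  vwc_surface <- vwc_bucket(met$rain, wet$start0, wet$min0, wet$max0,
                            k_dry = 0.004, infil = 0.006)
  vwc_30 <- vwc_bucket(met$rain, wet$start30, wet$min30, wet$max30,
                       k_dry = 0.006, infil = 0.012)
  vwc_10 <- 0.7 * vwc_surface + 0.3 * vwc_30
  vwc_20 <- 0.35 * vwc_surface + 0.65 * vwc_30

  w <- function(v) wfps(v, bd, pd)
  wfps_surface <- w(vwc_surface)
  o2 <- pmax(2, 20.9 - 0.10 * wfps_surface + stats::rnorm(n, 0, 0.3))
  thaw_depth <- 20 + 45 * (met$doy - min(met$doy)) /
    max(1, diff(range(met$doy))) +
    switch(vegetation, lichen = 5, shrub = 0, tussock = -8)

  tibble::tibble(
    vegetation = vegetation, time = met$time,
    t_soil_surface = t_surface, t_soil_10 = t_10,
    t_soil_20 = t_20, t_soil_30 = t_30,
    vwc_surface = vwc_surface, vwc_10 = vwc_10,
    vwc_20 = vwc_20, vwc_30 = vwc_30,
    wfps_surface = wfps_surface, wfps_10 = w(vwc_10),
    wfps_20 = w(vwc_20), wfps_30 = w(vwc_30),
    o2 = o2, thaw_depth = thaw_depth, bd = bd, pd = pd
  )
}
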