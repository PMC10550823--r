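#' Generative ground-truth flux model
#'
#' Parameterizes the hourly "true" CH4 flux of each chamber as a function
#' of hour-of-day, day-of-year, water-filled pore space, (lagged) surface
#' soil temperature and ecosystem respiration. The default configuration
#' emulates the behaviour of well-drained upland tundra:
#'
#' * lichen and shrub footprints are persistent CH4 sinks (negative flux),
#'   with uptake magnitude increasing as the soil dries;
#' * the diel uptake peak sits in the afternoon (around 15:30) in June and
#'   migrates to the night (around 01:30) by August, via a day-weight that
#'   shifts across the season;
#' * uptake is coupled to ecosystem respiration anomalies;
#' * surface soil temperature acts with a configurable lag (default 2 h);
#' * tussock chambers switch to emission only when WFPS at 30 cm exceeds
#'   a wetness threshold (default 80%).
#'
#' @param uptake_base Named numeric: baseline uptake magnitude per
#'   vegetation type, mg CH4 m^-2 h^-1 (positive numbers; the flux sign
#'   is applied internally).
#' @param moisture_sens Sensitivity of uptake to WFPS; the multiplicative
#'   moisture term is `exp(moisture_sens * (wfps_ref - WFPS) / 100)`.
#' @param wfps_ref Reference WFPS (%) at which the moisture term is 1.
#' @param temp_q10 Q10-style multiplier of uptake per 10 degC of lagged
#'   surface soil temperature.
#' @param t_ref Reference soil temperature, degC.
#' @param lag_tsoil Lag (hours) at which surface soil temperature acts on
#'   the flux.
#' @param er_coupling Named numeric per vegetation type: uptake is scaled
#'   multiplicatively by `exp(er_coupling * (ER - mean(ER)))` (units: per
#'   mg CO2 m^-2 h^-1 of ER anomaly), so respiration pulses deepen uptake
#'   without ever flipping its sign.
#' @param diel_amp Amplitude of the diel modulation (unitless; peak
#'   uptake is `(1 + diel_amp)` times the diel baseline).
#' @param peak_day_hour,peak_night_hour Centre of the afternoon (June) and
#'   nocturnal (August) uptake peaks, local hours.
#' @param sigma_hour Width (h) of the diel peaks.
#' @param shift_start_doy,shift_end_doy Season window over which the diel
#'   weight moves from the afternoon peak to the nocturnal peak.
#' @param tussock_wfps_threshold WFPS at 30 cm (%) above which tussock
#'   switches to net emission.
#' @param tussock_emission_max Maximum tussock emission rate at full
#'   saturation, mg CH4 m^-2 h^-1.
#' @param noise_sd Standard deviation of the hourly flux noise,
#'   mg CH4 m^-2 h^-1.
#' @param er_corr Optional target correlation magnitude between CH4 flux
#'   and ER. When set, the flux anomaly is constructed directly as a
#'   correlated mixture of the standardized ER series and white noise
#'   (population correlation `-er_corr`, so R^2 of a flux-on-ER
#'   regression is `er_corr^2`), and all other drivers are ignored. Used
#'   for calibration experiments.
#'
#' @return A list of class `truth_model`.
#' @export
truth_model <- function(uptake_base = c(lichen = 0.012, shrub = 0.009,
                                        tussock = 0.008),
                        moisture_sens = 1.6, wfps_ref = 30,
                        temp_q10 = 2.2, t_ref = 8, lag_tsoil = 2,
                        er_coupling = c(lichen = 3e-3, shrub = 6e-3,
                                        tussock = 3e-3),
                        diel_amp = 1.3,
                        peak_day_hour = 15.5, peak_night_hour = 1.5,
                        sigma_hour = 2.5,
                        shift_start_doy = 178, shift_end_doy = 212,
                        tussock_wfps_threshold = 80,
                        tussock_emission_max = 0.20,
                        noise_sd = 0.003,
                        er_corr = NULL) {
  structure(as.list(environment()), class = "truth_model")
}

# seasonal weight moving the diel peak from afternoon to night
diel_shift_weight <- function(doy, model) {
  pmin(1, pmax(0, (doy - model$shift_start_doy) /
                 (model$shift_end_doy - model$shift_start_doy)))
}

diel_factor <- function(hour, doy, model) {
  w <- diel_shift_weight(doy, model)
  1 + model$diel_amp *
    ((1 - w) * hour_bump(hour, model$peak_day_hour, model$sigma_hour) +
       w * hour_bump(hour, model$peak_night_hour, model$sigma_hour))
}

lag_fill <- function(x, lag) {
  if (lag <= 0) return(x)
  c(rep(x[1], lag), x[seq_len(length(x) - lag)])
}

# hourly true CH4 flux for one chamber (deterministic part + noise drawn
# by the caller's RNG state)
eval_truth <- function(model, vegetation, met, soil, er) {
  n <- nrow(met)
  base <- model$uptake_base[[vegetation]]
  if (!is.null(model$er_corr)) {
    r <- model$er_corr
    z_er <- as.numeric(scale(er))
    eps <- stats::rnorm(n)
    return(-base * (1 + 0.4 * (r * z_er + sqrt(1 - r^2) * eps)))
  }
  moist <- exp(model$moisture_sens * (model$wfps_ref - soil$wfps_surface) / 100)
  t_lag <- lag_fill(soil$t_soil_surface, model$lag_tsoil)
  temp <- model$temp_q10^((t_lag - model$t_ref) / 10)
  diel <- diel_factor(met$hour, met$doy, model)
  er_fac <- exp(model$er_coupling[[vegetation]] * (er - mean(er)))
  flux <- -base * moist * temp * diel * er_fac
  if (vegetation == "tussock") {
    thr <- model$tussock_wfps_threshold
    wet <- pmax(0, soil$wfps_30 - thr) / (100 - thr)
    flux <- flux + model$tussock_emission_max * wet
  }
  flux + stats::rnorm(n, 0, model$noise_sd)
}

# hourly true ER (mg CO2 m^-2 h^-1) for one chamber. Three components:
# a Q10 response of 10 cm soil temperature (diel-damped), a diel cycle
# that migrates from afternoon to nocturnal across the season in step
# with the truth model's uptake peak (late-summer respiration pulses are
# not temperature-driven), and a slow multiplicative substrate-supply
# anomaly independent of temperature (labile-carbon rhizodeposition
# pulses), plus microsite offset and hourly variability.
eval_er_truth <- function(vegetation, soil, met, model, microsite = 1) {
  base <- switch(vegetation, lichen = 130, shrub = 260, tussock = 310)
  w <- diel_shift_weight(met$doy, model)
  er_diel <- 1 + 0.25 *
    ((1 - w) * hour_bump(met$hour, model$peak_day_hour, 3.5) +
       w * hour_bump(met$hour, model$peak_night_hour, 3.5))
  substrate <- exp(ar1(nrow(soil), 0.95, 0.06))
  er <- base * 2^((soil$t_soil_10 - 6) / 10) * er_diel * microsite *
    substrate
  er * exp(stats::rnorm(nrow(soil), 0, 0.08))
}

# hourly true GPP (mg CO2 m^-2 h^-1, negative = uptake) via PAR
# saturation curve
eval_gpp_truth <- function(vegetation, met, microsite = 1) {
  gmax <- switch(vegetation, lichen = 60, shrub = 420, tussock = 360)
  -gmax * met$par / (met$par + 400) * microsite *
    exp(stats::rnorm(nrow(met), 0, 0.06))
}
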