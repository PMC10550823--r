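#' Simulate one chamber closure concentration trace
#'
#' Produces the 1 Hz (or `analyzer$sample_rate`) headspace concentration
#' series recorded during a single lid closure, given the true surface
#' flux. In `"linear"` mode the trace has exactly constant dC/dt, the
#' inversion of the chamber unit-conversion formula
#' ([concentration_to_flux()]). In `"saturating"` mode the trace follows
#' the single-exponential headspace model
#' `C(t) = phi + (C0 - phi) * exp(-kappa t)` whose *initial* slope
#' corresponds to the true flux. Gaussian analyser noise with the
#' per-gas 1-sigma precision is then added.
#'
#' @param true_flux True surface flux, mg m^-2 h^-1 (negative = uptake).
#' @param gas `"ch4"` or `"co2"`.
#' @param chamber One-row chamber spec tibble.
#' @param analyzer An [analyzer_spec()].
#' @param mode `"linear"` or `"saturating"`.
#' @param duration Closure length in seconds (default 180; samples run
#'   from t = 0 to t = duration inclusive, i.e. 181 samples at 1 Hz).
#' @param t_air Chamber air temperature, degC.
#' @param pressure Ambient pressure, kPa.
#' @param c0 Ambient concentration at lid close, native gas unit
#'   (ppb CH4 / ppm CO2).
#' @param kappa Rate constant of the saturating model, s^-1 (default
#'   1/600, detectable curvature within a 3-min closure).
#' @param noise Add analyser noise? Set `FALSE` for noiseless traces.
#' @param seed Optional integer seed (only the trace noise is drawn).
#' @param time Closure start time (POSIXct), attached as metadata.
#' @param par_chamber PAR inside the chamber, attached as metadata.
#' @param pressure_in,pressure_out Chamber line pressures (kPa), attached
#'   as metadata.
#'
#' @return A long closure-series tibble: `chamber_id`, `time`, `t_s`,
#'   `gas`, `conc`, `t_chamber`, `pressure_ambient`, `pressure_in`,
#'   `pressure_out`, `par_chamber`.
#' @export
#' @examples
#' ch <- chamber_spec("a", "lichen", "opaque", effective_volume = 30)
#' tr <- simulate_closure(-0.02, "ch4", ch, mode = "linear", noise = FALSE)
#' nrow(tr)  # 181 samples
simulate_closure <- function(true_flux, gas = "ch4", chamber,
                             analyzer = analyzer_spec(),
                             mode = c("linear", "saturating"),
                             duration = 180, t_air = 15,
                             pressure = 101.325, c0 = NULL,
                             kappa = 1 / 600, noise = TRUE, seed = NULL,
                             time = as.POSIXct("2021-07-01 12:00:00",
                                               tz = "UTC"),
                             par_chamber = 0,
                             pressure_in = 7.5, pressure_out = 7.5) {
  mode <- match.arg(mode)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  validate_chambers(chamber)
  if (mode == "saturating" && (!is.finite(kappa) || kappa <= 0)) {
    stop("saturating mode requires a curvature parameter kappa > 0",
         call. = FALSE)
  }
  if (is.null(c0)) c0 <- switch(gas, ch4 = 1950, co2 = 420)
  if (!is.null(seed)) set.seed(seed)

  t_s <- seq(0, duration, by = 1 / analyzer$sample_rate)
  slope0 <- flux_to_slope(true_flux, gas, chamber, t_air, pressure)
  conc <- if (mode == "linear") {
    c0 + slope0 * t_s
  } else {
    phi <- c0 + slope0 / kappa
    phi + (c0 - phi) * exp(-kappa * t_s)
  }
  if (noise) {
    conc <- conc + stats::rnorm(length(t_s), 0, analyzer$precision_1s[[gas]])
  }
  tibble::tibble(
    chamber_id = chamber$chamber_id, time = time, t_s = t_s,
    gas = gas, conc = conc, t_chamber = t_air,
    pressure_ambient = pressure, pressure_in = pressure_in,
    pressure_out = pressure_out, par_chamber = par_chamber
  )
}

# bounded analyser drift: random walk re-anchored to zero every 24 h and
# clipped to +/- the printed 24-h drift spec
drift_series <- function(n_hours, drift_max) {
  if (n_hours == 0) return(numeric(0))
  step <- stats::rnorm(n_hours, 0, drift_max / 10)
  d <- numeric(n_hours)
  for (i in seq_len(n_hours)) {
    prev <- if (i %% 24 == 1) 0 else d[i - 1]   # daily re-anchor
    d[i] <- max(-drift_max, min(drift_max, prev + step[i]))
  }
  d
}
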