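#' Convert an initial concentration slope to a surface flux
#'
#' Standard static-chamber unit conversion. The initial rate of change of
#' the headspace mole fraction is scaled by the molar amount of air in the
#' chamber (ideal gas law), the molar mass of the gas and the footprint
#' area:
#'
#' flux = slope0 * (P V) / (R T) * M / A * 3600 * 1000
#'
#' with slope0 as mole fraction s^-1, P in Pa, V in m^3, T in K,
#' R = 8.314 J mol^-1 K^-1, M in g mol^-1 and A in m^2, giving
#' mg m^-2 h^-1. The sign of the slope is preserved: negative slopes
#' (concentration drawdown) are uptake.
#'
#' @param slope0 Initial concentration slope in the gas's native unit per
#'   second (ppb s^-1 for CH4, ppm s^-1 for CO2).
#' @param gas `"ch4"` or `"co2"`.
#' @param chamber One row of a chamber specification tibble
#'   (see [chamber_spec()]).
#' @param t_chamber Chamber air temperature, degrees C.
#' @param pressure Ambient air pressure, kPa.
#'
#' @return Flux in mg m^-2 h^-1.
#' @export
#' @examples
#' ch <- chamber_spec("a", "lichen", "opaque", effective_volume = 30)
#' concentration_to_flux(0.01, "ch4", ch, t_chamber = 15, pressure = 101.325)
concentration_to_flux <- function(slope0, gas, chamber, t_chamber, pressure) {
  stopifnot(nrow(chamber) == 1)
  if (!is.finite(t_chamber) || t_chamber <= -80) {
    stop("t_chamber must be a plausible air temperature (> -80 degC)",
         call. = FALSE)
  }
  if (!is.finite(pressure) || pressure <= 0) {
    stop("pressure must be positive (kPa)", call. = FALSE)
  }
  validate_chambers(chamber)
  R_gas <- 8.314
  n_air <- (pressure * 1e3) * (chamber$effective_volume * 1e-3) /
    (R_gas * (t_chamber + 273.15))         # mol of air in the headspace
  slope_molfrac <- slope0 * gas_unit_to_molfrac(gas)
  slope_molfrac * n_air * gas_molar_mass(gas) / chamber$footprint_area *
    3600 * 1e3
}

# inverse of concentration_to_flux: flux (mg m^-2 h^-1) -> slope in native
# concentration unit per second. Used by the closure simulator.
flux_to_slope <- function(flux, gas, chamber, t_chamber, pressure) {
  flux / concentration_to_flux(1, gas, chamber, t_chamber, pressure)
}

#' Convert a CO2 flux from mg m^-2 h^-1 to umol m^-2 s^-1
#'
#' @param flux_mg CO2 flux in mg CO2 m^-2 h^-1.
#' @return Flux in umol CO2 m^-2 s^-1.
#' @export
co2_mg_to_umol <- function(flux_mg) {
  flux_mg / 44.01 * 1e3 / 3600
}

drop_deadband <- function(series, gas, deadband_s) {
  s <- series[series$gas == gas & series$t_s >= deadband_s, , drop = FALSE]
  s[order(s$t_s), , drop = FALSE]
}

fit_stats <- function(obs, fitted, n_par) {
  resid <- obs - fitted
  rss <- sum(resid^2)
  tss <- sum((obs - mean(obs))^2)
  n <- length(obs)
  # Gaussian AICc from the residual sum of squares
  k <- n_par + 1
  aic <- n * log(rss / n + .Machine$double.xmin) + 2 * k
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  list(
    r2 = if (tss > 0) 1 - rss / tss else 0,
    rmse = sqrt(rss / n),
    aicc = aicc,
    n = n
  )
}

#' Linear fit of a closure concentration trace
#'
#' Ordinary least-squares fit of concentration against time after
#' discarding the dead-band (initial mixing transient). The slope is the
#' estimated initial concentration change rate.
#'
#' @param series Closure series tibble with columns `t_s`, `gas`, `conc`
#'   (long format, one row per sample per gas).
#' @param gas Gas to fit, `"ch4"` or `"co2"`.
#' @param deadband_s Seconds discarded at the start of the closure
#'   (default 20).
#' @param min_points Minimum usable samples after dead-band removal
#'   (default 30); fewer returns a flagged, non-computed result.
#'
#' @return A list with `slope0`, `intercept`, `r2`, `rmse`, `aicc`,
#'   `n_points`, `ok` and `flags`.
#' @export
fit_linear <- function(series, gas, deadband_s = 20, min_points = 30) {
  s <- drop_deadband(series, gas, deadband_s)
  if (nrow(s) < min_points) {
    return(list(slope0 = NA_real_, intercept = NA_real_, r2 = NA_real_,
                rmse = NA_real_, aicc = Inf, n_points = nrow(s),
                ok = FALSE, flags = "insufficient_data"))
  }
  X <- cbind(1, s$t_s)
  cf <- stats::.lm.fit(X, s$conc)$coefficients
  st <- fit_stats(s$conc, X %*% cf, n_par = 2)
  list(slope0 = cf[2], intercept = cf[1], r2 = st$r2, rmse = st$rmse,
       aicc = st$aicc, n_points = st$n, ok = TRUE, flags = character(0))
}

#' Saturating exponential fit of a closure concentration trace
#'
#' Nonlinear least-squares fit of the single-exponential headspace model
#' `C(t) = phi + (C0 - phi) * exp(-kappa * t)`, which captures the
#' feedback of the accumulating (or depleting) headspace concentration on
#' the diffusion gradient. The reported initial slope is
#' `kappa * (phi - C0)`, the concentration change rate at lid close.
#'
#' @inheritParams fit_linear
#' @return A list with `c0`, `phi`, `kappa`, `kappa_se`, `slope0`, fit
#'   statistics, `ok` and `flags`. A non-converging solver yields
#'   `ok = FALSE` with flag `"exp_fit_failed"` (fit selection then falls
#'   back to the linear estimate).
#' @export
fit_exponential <- function(series, gas, deadband_s = 20, min_points = 30) {
  s <- drop_deadband(series, gas, deadband_s)
  failed <- list(c0 = NA_real_, phi = NA_real_, kappa = NA_real_,
                 kappa_se = NA_real_, slope0 = NA_real_, r2 = NA_real_,
                 rmse = NA_real_, aicc = Inf, n_points = nrow(s),
                 ok = FALSE, flags = "exp_fit_failed")
  if (nrow(s) < min_points) {
    failed$flags <- "insufficient_data"
    return(failed)
  }
  t0 <- s$t_s - s$t_s[1]
  # the model is linear in (c0, phi) for fixed kappa, so locate kappa by
  # profiling the 1-D residual sum of squares before the full fit; a
  # joint start from scratch stalls on the flat kappa ridge of
  # near-linear traces
  prof <- function(log_k) {
    e <- exp(-exp(log_k) * t0)
    sum(stats::.lm.fit(cbind(1, e), s$conc)$residuals^2)
  }
  opt <- stats::optimize(prof, interval = log(c(1e-6, 1)), tol = 1e-10)
  k0 <- exp(opt$minimum)
  beta <- stats::.lm.fit(cbind(1, exp(-k0 * t0)), s$conc)$coefficients
  start <- list(c0 = beta[1] + beta[2], phi = beta[1], kappa = k0)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      conc ~ phi + (c0 - phi) * exp(-kappa * tt),
      data = list(conc = s$conc, tt = t0),
      start = start,
      lower = c(c0 = -Inf, phi = -Inf, kappa = 1e-6),
      upper = c(c0 = Inf, phi = Inf, kappa = 1),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || !all(is.finite(stats::coef(fit)))) return(failed)
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["kappa", "Std. Error"],
                 error = function(e) NA_real_)
  st <- fit_stats(s$conc, stats::fitted(fit), n_par = 3)
  # report the slope back-extrapolated to lid close (t = 0): the fitted
  # exponential started at lid close, the dead band only hides its start
  slope0 <- unname(cf["kappa"] * (cf["phi"] - cf["c0"]) *
                     exp(cf["kappa"] * s$t_s[1]))
  list(c0 = unname(cf["c0"]), phi = unname(cf["phi"]),
       kappa = unname(cf["kappa"]), kappa_se = se,
       slope0 = slope0,
       r2 = st$r2, rmse = st$rmse, aicc = st$aicc, n_points = st$n,
       ok = TRUE, flags = character(0))
}

#' Choose between linear and exponential closure fits
#'
#' CH4 headspace changes over a 3-min closure are typically small, so the
#' linear estimator is preferred; the exponential fit is selected only
#' when the implied flux magnitude exceeds a threshold *and* the
#' exponential model fits better (smaller AICc). CO2 changes are large
#' enough that the saturating model is preferred whenever its rate
#' constant is significantly positive; otherwise the linear fit is kept.
#' Degenerate cases (failed exponential fit) always fall back to linear.
#'
#' @param linear_result Result of [fit_linear()].
#' @param exp_result Result of [fit_exponential()].
#' @param gas `"ch4"` or `"co2"`.
#' @param chamber,t_chamber,pressure Passed to [concentration_to_flux()]
#'   to express the exponential initial slope as a flux for thresholding.
#' @param ch4_exp_threshold Flux magnitude (mg CH4 m^-2 h^-1) above which
#'   the exponential fit may be selected for CH4 (default 0.05).
#' @param kappa_z One-sided z threshold for "kappa significantly > 0"
#'   (default 1.645, 5% level).
#'
#' @return `"linear"` or `"exponential"`.
#' @export
select_fit <- function(linear_result, exp_result, gas, chamber,
                       t_chamber, pressure,
                       ch4_exp_threshold = 0.05, kappa_z = 1.645) {
  if (!isTRUE(exp_result$ok) || !is.finite(exp_result$slope0)) {
    return("linear")
  }
  if (gas == "ch4") {
    exp_flux <- concentration_to_flux(exp_result$slope0, gas, chamber,
                                      t_chamber, pressure)
    if (abs(exp_flux) > ch4_exp_threshold &&
        exp_result$aicc < linear_result$aicc) {
      return("exponential")
    }
    return("linear")
  }
  # co2: exponential unless kappa is not significantly > 0
  if (is.finite(exp_result$kappa_se) && exp_result$kappa_se > 0 &&
      exp_result$kappa / exp_result$kappa_se > kappa_z) {
    return("exponential")
  }
  "linear"
}

#' Estimate one flux from a closure concentration trace
#'
#' Orchestrates the full per-closure chain: dead-band trim, linear and
#' (optionally) exponential fits, fit selection and unit conversion.
#' Never raises on a fit failure; problems are recorded as QC flags.
#'
#' @param series Closure series tibble (long format) with columns `t_s`,
#'   `gas`, `conc` and metadata columns `chamber_id`, `t_chamber`,
#'   `pressure_ambient` (used when the explicit arguments are missing).
#' @param gas `"ch4"` or `"co2"`.
#' @param chamber One-row chamber spec.
#' @param t_chamber,pressure Chamber air temperature (degC) and ambient
#'   pressure (kPa); defaulted from the series metadata columns if present.
#' @param deadband_s,min_points,ch4_exp_threshold See [fit_linear()] and
#'   [select_fit()].
#' @param try_exponential If `FALSE`, skip the exponential fit entirely
#'   (useful for bulk CH4 processing where the linear fit dominates).
#'
#' @return A one-row tibble (`FluxEstimate`): `gas`, `flux`
#'   (mg m^-2 h^-1, negative = uptake), `fit_type`, `slope0`, `fit_r2`,
#'   `fit_rmse`, `n_points`, `deadband_s`, `qc_flags`
#'   (semicolon-separated, `""` if clean).
#' @export
compute_flux <- function(series, gas, chamber,
                         t_chamber = NULL, pressure = NULL,
                         deadband_s = 20, min_points = 30,
                         ch4_exp_threshold = 0.05,
                         try_exponential = TRUE) {
  if (is.null(t_chamber)) t_chamber <- series$t_chamber[1]
  if (is.null(pressure)) pressure <- series$pressure_ambient[1]
  lin <- fit_linear(series, gas, deadband_s, min_points)
  if (!lin$ok) {
    return(tibble::tibble(
      gas = gas, flux = NA_real_, fit_type = NA_character_,
      slope0 = NA_real_, fit_r2 = NA_real_, fit_rmse = NA_real_,
      n_points = lin$n_points, deadband_s = deadband_s,
      qc_flags = paste(lin$flags, collapse = ";")
    ))
  }
  flags <- character(0)
  if (try_exponential) {
    ex <- fit_exponential(series, gas, deadband_s, min_points)
    if (!ex$ok) flags <- c(flags, ex$flags)
  } else {
    ex <- list(ok = FALSE, slope0 = NA_real_)
  }
  type <- select_fit(lin, ex, gas, chamber, t_chamber, pressure,
                     ch4_exp_threshold = ch4_exp_threshold)
  res <- if (type == "exponential") ex else lin
  flux <- concentration_to_flux(res$slope0, gas, chamber, t_chamber, pressure)
  tibble::tibble(
    gas = gas, flux = flux, fit_type = type, slope0 = res$slope0,
    fit_r2 = res$r2, fit_rmse = res$rmse, n_points = res$n_points,
    deadband_s = deadband_s, qc_flags = paste(flags, collapse = ";")
  )
}

#' Estimate fluxes for every closure in a campaign table
#'
#' Applies [compute_flux()] to each (chamber, closure start, gas) group of
#' a long-format closures table.
#'
#' @param closures Long closures tibble: `chamber_id`, `time`, `t_s`,
#'   `gas`, `conc`, `t_chamber`, `pressure_ambient` and optionally
#'   `pressure_in`, `pressure_out`, `par_chamber`.
#' @param chambers Chamber specification tibble.
#' @param gases Character vector of gases to process.
#' @param ... Passed to [compute_flux()].
#'
#' @return Tibble with one row per chamber x closure x gas: `chamber_id`,
#'   `time` plus all [compute_flux()] columns, with `pressure_in`,
#'   `pressure_out` carried through when present.
#' @export
compute_fluxes <- function(closures, chambers, gases = c("ch4", "co2"), ...) {
  keys <- unique(closures[, c("chamber_id", "time")])
  out <- vector("list", nrow(keys) * length(gases))
  k <- 0L
  for (i in seq_len(nrow(keys))) {
    sel <- closures$chamber_id == keys$chamber_id[i] &
      closures$time == keys$time[i]
    ser <- closures[sel, , drop = FALSE]
    ch <- chambers[chambers$chamber_id == keys$chamber_id[i], , drop = FALSE]
    if (nrow(ch) != 1) {
      stop("closures refer to chamber '", keys$chamber_id[i],
           "' absent from the chamber spec", call. = FALSE)
    }
    for (g in intersect(gases, unique(ser$gas))) {
      k <- k + 1L
      est <- compute_flux(ser, g, ch, ...)
      est$chamber_id <- keys$chamber_id[i]
      est$time <- keys$time[i]
      for (col in c("pressure_in", "pressure_out")) {
        if (col %in% names(ser)) est[[col]] <- ser[[col]][1]
      }
      out[[k]] <- est
    }
  }
  res <- dplyr::bind_rows(out[seq_len(k)])
  dplyr::relocate(res, "chamber_id", "time")
}

#' Partition net ecosystem exchange into respiration and photosynthesis
#'
#' Opaque chambers measure ecosystem respiration (ER) directly. For each
#' vegetation type and hour, ER is the mean CO2 flux of the opaque
#' chambers (n = 3 in the default layout); transparent chambers measure
#' net ecosystem exchange (NEE) and their gross primary production is
#' GPP = NEE - ER. Hours without any opaque partner yield missing GPP,
#' never zero.
#'
#' @param flux_table Hourly flux tibble with columns `chamber_id`, `time`,
#'   `gas`, `flux` containing CO2 rows.
#' @param chambers Chamber spec tibble (for vegetation and transparency).
#'
#' @return The CO2 rows of `flux_table` joined with `vegetation`,
#'   `transparency` and new columns `er` and `gpp` (both mg CO2 m^-2
#'   h^-1; `gpp` is `NA` for opaque chambers and for hours lacking ER).
#' @export
partition_gpp <- function(flux_table, chambers) {
  co2 <- dplyr::filter(flux_table, .data$gas == "co2")
  co2 <- dplyr::left_join(
    co2, chambers[, c("chamber_id", "vegetation", "transparency")],
    by = "chamber_id"
  )
  er_tbl <- co2 |>
    dplyr::filter(.data$transparency == "opaque") |>
    dplyr::group_by(.data$vegetation, .data$time) |>
    dplyr::summarise(er_veg = mean(.data$flux, na.rm = TRUE), .groups = "drop")
  co2 <- dplyr::left_join(co2, er_tbl, by = c("vegetation", "time"))
  co2 |>
    dplyr::mutate(
      er = dplyr::if_else(.data$transparency == "opaque",
                          .data$flux, .data$er_veg),
      gpp = dplyr::if_else(.data$transparency == "transparent",
                           .data$flux - .data$er_veg, NA_real_)
    ) |>
    dplyr::select(-"er_veg")
}
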