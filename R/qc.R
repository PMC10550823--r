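#' QC configuration
#'
#' Thresholds for the data-cleaning filters. The turbulence rule follows
#' the field protocol: fluxes measured between 23:00 and 07:00 local
#' standard time are excluded when friction velocity u* < 0.15 m s^-1
#' *and* wind speed (7 m) < 1.50 m s^-1 (all three conditions required).
#' Chamber line pressures are typically 7-8 kPa; the pressure filter
#' flags inconsistent inflow/outflow (|difference| above a tolerance) or
#' either line outside a plausible band.
#'
#' @param ustar_min u* threshold, m s^-1 (default 0.15).
#' @param wind_min Wind-speed threshold, m s^-1 (default 1.50).
#' @param night_start,night_end Night window, local hours; interpreted as
#'   the half-open interval `[night_start, night_end)` (defaults 23, 7).
#' @param pressure_tol Max |inflow - outflow| in kPa (default 2;
#'   `Inf` disables).
#' @param pressure_band Plausible band for either line pressure, kPa
#'   (default c(4, 12)).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(ustar_min = 0.15, wind_min = 1.50,
                      night_start = 23, night_end = 7,
                      pressure_tol = 2, pressure_band = c(4, 12)) {
  structure(as.list(environment()), class = "qc_config")
}

#' Flag closures with inconsistent chamber line pressures
#'
#' @param flux_table Flux tibble with columns `pressure_in`,
#'   `pressure_out` (kPa). If the columns are absent, every record is
#'   flagged `"pressure_unknown"` (kept, with a warning) rather than
#'   silently passed.
#' @param config A [qc_config()].
#' @return Character vector of flags per row: `""` (pass),
#'   `"pressure_inconsistent"` or `"pressure_unknown"`.
#' @export
pressure_filter <- function(flux_table, config = qc_config()) {
  if (!all(c("pressure_in", "pressure_out") %in% names(flux_table))) {
    warning("pressure channels missing; records flagged 'pressure_unknown' ",
            "and retained", call. = FALSE)
    return(rep("pressure_unknown", nrow(flux_table)))
  }
  p_in <- flux_table$pressure_in
  p_out <- flux_table$pressure_out
  bad <- abs(p_in - p_out) > config$pressure_tol |
    p_in < config$pressure_band[1] | p_in > config$pressure_band[2] |
    p_out < config$pressure_band[1] | p_out > config$pressure_band[2]
  bad[is.na(bad)] <- TRUE
  ifelse(bad, "pressure_inconsistent", "")
}

in_night_window <- function(hour, night_start, night_end) {
  if (night_start <= night_end) {
    hour >= night_start & hour < night_end
  } else {
    hour >= night_start | hour < night_end
  }
}

#' Flag night-time fluxes measured under poor atmospheric mixing
#'
#' A flux is flagged if and only if its local hour falls in the night
#' window `[23:00, 07:00)` *and* u* is below `ustar_min` *and* wind speed
#' is below `wind_min`. Records whose hour has no matching met record are
#' flagged `"met_missing"`.
#'
#' @param flux_table Flux tibble with a `time` column (hourly).
#' @param met Hourly met tibble with `time`, `u_star`, `wind_speed`.
#' @param config A [qc_config()].
#' @return Character vector of flags per row: `""`, `"low_turbulence"`
#'   or `"met_missing"`.
#' @export
turbulence_filter <- function(flux_table, met, config = qc_config()) {
  idx <- match(flux_table$time, met$time)
  hour <- as.integer(format(flux_table$time, "%H"))
  u <- met$u_star[idx]
  w <- met$wind_speed[idx]
  flag <- rep("", nrow(flux_table))
  flag[is.na(idx)] <- "met_missing"
  calm <- !is.na(idx) &
    in_night_window(hour, config$night_start, config$night_end) &
    u < config$ustar_min & w < config$wind_min
  flag[calm] <- "low_turbulence"
  flag
}

#' Apply all QC filters and report discard fractions
#'
#' Runs the pressure and turbulence filters, removes flagged records, and
#' summarises per-gas counts and percentages discarded by each filter.
#' Records flagged `"insufficient_data"` by the flux stage (carried in a
#' `qc_flags` column) are also discarded. Cleaning is idempotent: a
#' second pass over the cleaned table discards nothing.
#'
#' @param flux_table Hourly flux tibble with `time`, `gas`, `flux` and
#'   (optionally) `pressure_in`/`pressure_out` and `qc_flags`.
#' @param met Hourly met tibble.
#' @param config A [qc_config()].
#' @return A list with `fluxes` (cleaned tibble, with a `qc_flags`
#'   column recording the flags of retained rows, normally all `""`) and
#'   `summary` (per-gas tibble: `gas`, `n_total`, `n_pressure`,
#'   `n_turbulence`, `n_fit`, `n_discarded`, `pct_discarded`).
#' @export
apply_qc <- function(flux_table, met, config = qc_config()) {
  p_flag <- if (all(c("pressure_in", "pressure_out") %in% names(flux_table))) {
    pressure_filter(flux_table, config)
  } else {
    rep("", nrow(flux_table))
  }
  t_flag <- turbulence_filter(flux_table, met, config)
  fit_flag <- if ("qc_flags" %in% names(flux_table)) {
    ifelse(grepl("insufficient_data", flux_table$qc_flags) |
             is.na(flux_table$flux), "fit_failed", "")
  } else {
    ifelse(is.na(flux_table$flux), "fit_failed", "")
  }
  drop_p <- p_flag == "pressure_inconsistent"
  drop_t <- t_flag == "low_turbulence"
  drop_f <- fit_flag == "fit_failed"
  drop <- drop_p | drop_t | drop_f

  summary <- flux_table |>
    dplyr::mutate(.drop_p = drop_p, .drop_t = drop_t, .drop_f = drop_f,
                  .drop = drop) |>
    dplyr::group_by(.data$gas) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_pressure = sum(.data$.drop_p),
      n_turbulence = sum(.data$.drop_t),
      n_fit = sum(.data$.drop_f),
      n_discarded = sum(.data$.drop),
      pct_discarded = 100 * mean(.data$.drop),
      .groups = "drop"
    )
  cleaned <- flux_table[!drop, , drop = FALSE]
  cleaned$qc_flags <- ""
  list(fluxes = cleaned, summary = summary)
}

#' Write a QC summary to JSON
#'
#' @param qc Result of [apply_qc()].
#' @param path Output path for `qc_summary.json`.
#' @return `path`, invisibly.
#' @export
write_qc_summary <- function(qc, path) {
  jsonlite::write_json(qc$summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
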