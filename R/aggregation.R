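#' Water-filled pore space
#'
#' WFPS (%) = 100 * theta_v / (1 - BD / PD), the fraction of soil pore
#' volume occupied by water: volumetric water content divided by total
#' porosity from bulk density BD and particle density PD. Values beyond
#' saturation are clipped to 100 with a warning.
#'
#' @param theta_v Volumetric water content, m^3 m^-3 (0-1).
#' @param bd Bulk density, g cm^-3.
#' @param pd Particle density, g cm^-3 (default 2.65, mineral soil).
#' @return WFPS in percent, within \[0, 100\].
#' @export
#' @examples
#' wfps(0.31, bd = 1.0, pd = 2.65)  # ~49.8 %
wfps <- function(theta_v, bd, pd = 2.65) {
  if (any(bd >= pd) || any(bd <= 0)) {
    stop("requires particle density > bulk density > 0", call. = FALSE)
  }
  if (any(theta_v < 0 | theta_v > 1, na.rm = TRUE)) {
    stop("theta_v must lie in [0, 1]", call. = FALSE)
  }
  porosity <- 1 - bd / pd
  out <- 100 * theta_v / porosity
  if (any(out > 100, na.rm = TRUE)) {
    warning("theta_v exceeds porosity; WFPS clipped to 100%", call. = FALSE)
    out <- pmin(out, 100)
  }
  pmax(out, 0)
}

#' Daily flux sums with short-gap interpolation
#'
#' Sums hourly fluxes over each 24 h period per chamber. Days with fewer
#' than 24 hourly values but fewer than `max_gap` missing hours are
#' completed by linear interpolation across the gaps (constant extension
#' at day edges); days missing `max_gap` or more hours are reported as
#' missing.
#'
#' @param flux_table Hourly flux tibble with `chamber_id`, `time`, `flux`
#'   (one gas; filter first if mixed).
#' @param max_gap Missing-hour count at or above which a day is treated
#'   as missing (default 12).
#' @return Tibble: `chamber_id`, `date`, `flux_daily` (mg m^-2 d^-1, NA
#'   for missing days), `n_hours` (observed), `n_filled`.
#' @export
hourly_to_daily <- function(flux_table, max_gap = 12) {
  tb <- flux_table
  tb$date <- as.Date(tb$time)
  tb$hour <- as.integer(format(tb$time, "%H"))
  full <- tidyr::expand_grid(
    chamber_id = unique(tb$chamber_id),
    date = seq(min(tb$date), max(tb$date), by = "day"),
    hour = 0:23
  )
  full <- dplyr::left_join(full, tb[, c("chamber_id", "date", "hour", "flux")],
                           by = c("chamber_id", "date", "hour"))
  full |>
    dplyr::group_by(.data$chamber_id, .data$date) |>
    dplyr::summarise(
      n_hours = sum(!is.na(.data$flux)),
      n_filled = 24L - n_hours,
      flux_daily = if (n_filled >= max_gap) NA_real_ else {
        sum(zoo::na.approx(.data$flux, x = .data$hour, na.rm = FALSE,
                           rule = 2))
      },
      .groups = "drop"
    )
}

#' Season class of a timestamp
#'
#' June is early summer, July peak summer, August late summer; May and
#' September fall in the shoulder seasons (excluded from diel
#' composites).
#'
#' @param time POSIXct/Date vector, or numeric day-of-year (non-leap
#'   calendar assumed for numeric input).
#' @return Character vector: `"early"`, `"peak"`, `"late"` or
#'   `"shoulder"`.
#' @export
#' @examples
#' season_label(152)  # early (1 June)
#' season_label(213)  # late (1 August)
season_label <- function(time) {
  month <- if (is.numeric(time)) {
    as.integer(format(as.Date(time - 1, origin = "2021-01-01"), "%m"))
  } else {
    as.integer(format(time, "%m"))
  }
  dplyr::case_when(
    month == 6 ~ "early",
    month == 7 ~ "peak",
    month == 8 ~ "late",
    .default = "shoulder"
  )
}

join_vegetation <- function(flux_table, chambers) {
  if ("vegetation" %in% names(flux_table)) return(flux_table)
  dplyr::left_join(flux_table, chambers[, c("chamber_id", "vegetation")],
                   by = "chamber_id")
}

#' Diel composite of hourly fluxes
#'
#' Mean, sd and count of hourly fluxes per vegetation type x season class
#' (early/peak/late) x hour of day, pooling transparent and opaque
#' chambers and all years. Shoulder-season records are excluded. These
#' are raw composites; display smoothing is left to the caller.
#'
#' @param flux_table Cleaned hourly flux tibble with `chamber_id`,
#'   `time`, `flux`.
#' @param chambers Chamber spec tibble (for vegetation).
#' @return Tibble: `vegetation`, `season`, `hour`, `mean_flux`, `sd_flux`,
#'   `n`.
#' @export
diel_composite <- function(flux_table, chambers) {
  tb <- join_vegetation(flux_table, chambers)
  tb$season <- season_label(tb$time)
  tb$hour <- as.integer(format(tb$time, "%H"))
  tb |>
    dplyr::filter(.data$season != "shoulder") |>
    dplyr::group_by(.data$vegetation, .data$season, .data$hour) |>
    dplyr::summarise(
      mean_flux = mean(.data$flux, na.rm = TRUE),
      sd_flux = stats::sd(.data$flux, na.rm = TRUE),
      n = sum(!is.na(.data$flux)),
      .groups = "drop"
    )
}

#' Daytime-only sampling bias of daily flux budgets
#'
#' Quantifies the error committed by estimating a daily flux budget from
#' daytime measurements alone: for each chamber-day with full diel
#' coverage, the daytime-window mean flux is scaled to 24 h and compared
#' with the true daily sum. Bias is expressed in percent as
#' `100 * (estimate - truth) / truth`, so positive values mean the
#' daytime-only protocol overestimates the magnitude of the daily budget
#' (for uptake, i.e. negative daily sums, a more strongly negative
#' estimate gives a positive bias). Days whose daily sum is near zero
#' are excluded with a warning. Results are averaged per vegetation type
#' and season class.
#'
#' @param flux_table Hourly flux tibble (`chamber_id`, `time`, `flux`).
#' @param chambers Chamber spec tibble.
#' @param daytime_window Numeric length-2, local hours defining the
#'   daytime sampling window `[from, to)` (default `c(11, 15)`, when
#'   manual campaign visits cluster).
#' @param min_hours Minimum observed hours for a day to enter (default 24).
#' @param zero_tol Daily sums with absolute value below this (mg m^-2
#'   d^-1) are excluded as undefined (default 0.01).
#' @return Tibble: `vegetation`, `season`, `bias_pct` (mean over
#'   chamber-days), `n_days`.
#' @export
daytime_bias <- function(flux_table, chambers, daytime_window = c(11, 15),
                         min_hours = 24, zero_tol = 0.01) {
  tb <- join_vegetation(flux_table, chambers)
  tb$date <- as.Date(tb$time)
  tb$hour <- as.integer(format(tb$time, "%H"))
  tb$season <- season_label(tb$time)
  days <- tb |>
    dplyr::group_by(.data$chamber_id, .data$vegetation, .data$season,
                    .data$date) |>
    dplyr::summarise(
      n_hours = sum(!is.na(.data$flux)),
      daily_sum = sum(.data$flux),
      day_mean = mean(.data$flux[.data$hour >= daytime_window[1] &
                                   .data$hour < daytime_window[2]]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_hours >= min_hours, is.finite(.data$day_mean))
  near_zero <- abs(days$daily_sum) < zero_tol
  if (any(near_zero)) {
    warning(sum(near_zero), " day(s) with near-zero daily sum excluded ",
            "(bias undefined)", call. = FALSE)
    days <- days[!near_zero, , drop = FALSE]
  }
  days$bias_pct <- 100 * (days$day_mean * 24 - days$daily_sum) /
    days$daily_sum
  days |>
    dplyr::filter(.data$season != "shoulder") |>
    dplyr::group_by(.data$vegetation, .data$season) |>
    dplyr::summarise(bias_pct = mean(.data$bias_pct),
                     n_days = dplyr::n(), .groups = "drop")
}
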