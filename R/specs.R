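#' Chamber specification table
#'
#' Builds a table describing one or more flux chambers: their identity,
#' vegetation type, lid transparency and geometry. The footprint area is
#' always derived from the collar diameter, `pi * (d / 2)^2`.
#'
#' @param chamber_id Character vector of unique chamber labels.
#' @param vegetation Vegetation class of each chamber footprint; one of
#'   `"lichen"`, `"shrub"` or `"tussock"`.
#' @param transparency `"transparent"` (clear dome, measures NEE) or
#'   `"opaque"` (darkened dome, measures ecosystem respiration directly).
#' @param collar_diameter Inner collar diameter in m. Default 0.51 m.
#' @param effective_volume Total effective headspace volume (dome plus
#'   collar above-ground section) in litres; must lie in a plausible range
#'   for this chamber design (default validation band 10-100 l).
#'
#' @return A tibble with one row per chamber and columns `chamber_id`,
#'   `vegetation`, `transparency`, `collar_diameter`, `effective_volume`
#'   and the derived `footprint_area` (m^2).
#' @export
#' @examples
#' chamber_spec("ch01", "lichen", "opaque")
chamber_spec <- function(chamber_id, vegetation, transparency,
                         collar_diameter = 0.51, effective_volume = 35) {
  spec <- tibble::tibble(
    chamber_id = as.character(chamber_id),
    vegetation = vegetation,
    transparency = transparency,
    collar_diameter = collar_diameter,
    effective_volume = effective_volume
  )
  validate_chambers(spec)
  spec$footprint_area <- pi * (spec$collar_diameter / 2)^2
  spec
}

validate_chambers <- function(spec) {
  if (anyDuplicated(spec$chamber_id)) {
    stop("duplicated chamber_id in chamber specification", call. = FALSE)
  }
  if (!all(spec$vegetation %in% c("lichen", "shrub", "tussock"))) {
    stop("vegetation must be one of 'lichen', 'shrub', 'tussock'", call. = FALSE)
  }
  if (!all(spec$transparency %in% c("transparent", "opaque"))) {
    stop("transparency must be 'transparent' or 'opaque'", call. = FALSE)
  }
  if (any(!is.finite(spec$collar_diameter)) || any(spec$collar_diameter <= 0)) {
    stop("collar_diameter must be positive", call. = FALSE)
  }
  if (any(!is.finite(spec$effective_volume)) || any(spec$effective_volume <= 0)) {
    stop("effective_volume must be positive", call. = FALSE)
  }
  invisible(spec)
}

#' Default 18-chamber campaign layout
#'
#' Six replicate chambers on each of the three dominant upland tundra
#' vegetation types (lichen, shrub, tussock); within each vegetation type
#' three chambers are opaque and three transparent. Effective volumes are
#' spread evenly over 30-45 l to mimic differing collar insertion depths.
#'
#' @return A chamber specification tibble with 18 rows (see [chamber_spec()]).
#' @export
default_chambers <- function() {
  veg <- rep(c("lichen", "shrub", "tussock"), each = 6)
  transp <- rep(rep(c("opaque", "transparent"), each = 3), times = 3)
  chamber_spec(
    chamber_id = sprintf("ch%02d", seq_len(18)),
    vegetation = veg,
    transparency = transp,
    collar_diameter = 0.51,
    effective_volume = seq(30, 45, length.out = 18)
  )
}

#' Gas analyser specification
#'
#' Noise model of the greenhouse-gas analyser attached to the chamber
#' multiplexer: 1-sigma precision of a 1 s reading per gas, the maximum
#' drift over 24 h, and the sampling rate.
#'
#' @param precision_1s Named numeric vector: 1-sigma noise sd of a single
#'   1 s reading, in the native unit of each gas (ppb for CH4, ppm for
#'   CO2). Defaults to 1 ppb CH4 and 0.3 ppm (300 ppb) CO2.
#' @param drift_24h Named numeric vector: maximum drift over 24 h in the
#'   same units (default 5 ppb CH4, 0.3 ppm CO2).
#' @param sample_rate Sampling rate in Hz (default 1).
#'
#' @return An object of class `analyzer_spec` (a named list).
#' @export
analyzer_spec <- function(precision_1s = c(ch4 = 1, co2 = 0.3),
                          drift_24h = c(ch4 = 5, co2 = 0.3),
                          sample_rate = 1) {
  if (any(precision_1s < 0) || any(drift_24h < 0) || sample_rate <= 0) {
    stop("analyzer noise parameters must be >= 0 and sample_rate > 0",
         call. = FALSE)
  }
  structure(
    list(precision_1s = precision_1s, drift_24h = drift_24h,
         sample_rate = sample_rate),
    class = "analyzer_spec"
  )
}

# native concentration unit per gas: CH4 in ppb, CO2 in ppm
gas_unit_to_molfrac <- function(gas) {
  switch(gas, ch4 = 1e-9, co2 = 1e-6,
         stop("unknown gas '", gas, "'", call. = FALSE))
}

gas_molar_mass <- function(gas) {
  switch(gas, ch4 = 16.04, co2 = 44.01,
         stop("unknown gas '", gas, "'", call. = FALSE))
}
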