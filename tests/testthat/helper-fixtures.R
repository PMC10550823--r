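# shared fixtures: small chambers and short campaigns, built in code

one_chamber <- function(volume = 30) {
  ch <- chamber_spec("a", "lichen", "opaque", effective_volume = volume)
  # fixed reference footprint used by the hand-derived conversion values
  ch$footprint_area <- 0.204
  ch
}

short_campaign <- function(seed = 1, days = 14, start = 172, ...) {
  simulate_campaign(
    campaign_config(season = season_config(start_doy = start,
                                           end_doy = start + days - 1), ...),
    seed = seed
  )
}

# hourly flux table spanning given hours with constant flux
constant_flux_table <- function(flux = -0.02, hours = 0:23,
                                chamber_id = "a",
                                date = "2021-07-01") {
  tibble::tibble(
    chamber_id = chamber_id,
    time = as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + hours * 3600,
    gas = "ch4",
    flux = flux
  )
}
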