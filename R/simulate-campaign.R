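#' Campaign configuration
#'
#' Bundles everything the campaign simulator needs: chamber layout,
#' season, analyser, generative truth model, ambient baselines and
#' nuisance rates.
#'
#' @param chambers Chamber spec tibble (default [default_chambers()]:
#'   18 chambers, 6 per vegetation type, 3 opaque + 3 transparent).
#' @param season A [season_config()].
#' @param analyzer An [analyzer_spec()].
#' @param truth A [truth_model()].
#' @param ambient Named numeric ambient baselines at lid close
#'   (ppb CH4, ppm CO2); site values are not universal, so these are
#'   conventional northern-hemisphere numbers and fully configurable.
#' @param pressure_fault_rate Fraction of chamber-hours given a broken
#'   pressure line (out-of-band line pressures), exercising the pressure
#'   QC filter. Default 0.
#' @param closure_duration Closure length, s (default 180).
#'
#' @return A list of class `campaign_config`.
#' @export
campaign_config <- function(chambers = default_chambers(),
                            season = season_config(),
                            analyzer = analyzer_spec(),
                            truth = truth_model(),
                            ambient = c(ch4 = 1950, co2 = 420),
                            pressure_fault_rate = 0,
                            closure_duration = 180) {
  validate_chambers(chambers)
  if (nrow(chambers) < 1) stop("config names no chambers", call. = FALSE)
  structure(as.list(environment()), class = "campaign_config")
}

#' Simulate a full automated-chamber campaign
#'
#' Generates one seeded campaign: hourly meteorology and soil state, a
#' ground-truth table of hourly CH4 flux, ER, GPP and NEE per chamber,
#' and per-chamber microsite factors. Closure-level concentration traces
#' are generated on demand with [simulate_closures()] (they are bulky and
#' most analyses operate on the hourly tables).
#'
#' Reproducibility: all randomness flows from the single `seed` through a
#' fixed splitting scheme (one derived stream per component: met, soil
#' profiles, chamber microsites, truth noise, pressure faults, analyser
#' drift), so the same seed reproduces the campaign exactly.
#'
#' @param config A [campaign_config()].
#' @param seed Integer seed.
#'
#' @return A list of class `synthetic_campaign`: `chambers`, `met`,
#'   `soil`, `truth` (tibble: `chamber_id`, `vegetation`, `transparency`,
#'   `time`, `doy`, `hour`, `flux_true` (CH4), `er_true`, `gpp_true`,
#'   `nee_true`, `co2_true`, `pressure_in`, `pressure_out`), `drift`
#'   (hourly analyser drift per gas), `config`, `seed`.
#' @export
simulate_campaign <- function(config = campaign_config(), seed = 1) {
  stopifnot(inherits(config, "campaign_config"))
  env <- simulate_met(config$season, seed)
  met <- env$met
  soil <- env$soil
  n <- nrow(met)
  chambers <- config$chambers

  set.seed(split_seed(seed, 11))
  microsite <- stats::setNames(exp(stats::rnorm(nrow(chambers), 0, 0.12)),
                               chambers$chamber_id)

  set.seed(split_seed(seed, 12))
  truth <- vector("list", nrow(chambers))
  for (i in seq_len(nrow(chambers))) {
    ch <- chambers[i, ]
    s <- soil[soil$vegetation == ch$vegetation, ]
    er <- eval_er_truth(ch$vegetation, s, met, config$truth,
                        microsite[[ch$chamber_id]])
    gpp <- eval_gpp_truth(ch$vegetation, met, microsite[[ch$chamber_id]])
    flux <- eval_truth(config$truth, ch$vegetation, met, s, er)
    nee <- er + gpp
    truth[[i]] <- tibble::tibble(
      chamber_id = ch$chamber_id, vegetation = ch$vegetation,
      transparency = ch$transparency, time = met$time,
      doy = met$doy, hour = met$hour,
      flux_true = flux, er_true = er, gpp_true = gpp, nee_true = nee,
      co2_true = if (ch$transparency == "opaque") er else nee
    )
  }
  truth <- dplyr::bind_rows(truth)

  set.seed(split_seed(seed, 13))
  nt <- nrow(truth)
  p_in <- 7.5 + stats::rnorm(nt, 0, 0.15)
  p_out <- p_in + stats::rnorm(nt, 0, 0.05)
  fault <- stats::runif(nt) < config$pressure_fault_rate
  p_out[fault] <- stats::runif(sum(fault), 0, 2)   # broken/blocked line
  truth$pressure_in <- p_in
  truth$pressure_out <- p_out

  set.seed(split_seed(seed, 14))
  drift <- tibble::tibble(
    time = met$time,
    ch4 = drift_series(n, config$analyzer$drift_24h[["ch4"]]),
    co2 = drift_series(n, config$analyzer$drift_24h[["co2"]])
  )

  structure(
    list(chambers = chambers, met = met, soil = soil, truth = truth,
         drift = drift, config = config, seed = seed),
    class = "synthetic_campaign"
  )
}

#' @export
print.synthetic_campaign <- function(x, ...) {
  cat("<synthetic_campaign>\n")
  cat("  chambers:", nrow(x$chambers), "|",
      paste(unique(x$chambers$vegetation), collapse = "/"), "\n")
  cat("  season: DOY", x$config$season$start_doy, "-",
      x$config$season$end_doy, x$config$season$year, "\n")
  cat("  hours:", nrow(x$met), " seed:", x$seed, "\n")
  invisible(x)
}

#' Generate closure traces for (a subset of) a campaign
#'
#' Builds the 1 Hz concentration traces for every chamber-hour of the
#' campaign, or for a subset of times, using the campaign's ground-truth
#' fluxes, ambient baselines and analyser drift. CH4 closures use linear
#' headspace dynamics; CO2 closures use the saturating exponential model
#' (the large CO2 gradients make the headspace feedback visible within
#' 3 minutes).
#'
#' @param campaign A [simulate_campaign()] result.
#' @param times Optional POSIXct vector of closure start hours to
#'   generate (default: all campaign hours).
#' @param gases Gases to generate.
#' @param noise Add analyser noise?
#' @param kappa_co2 Rate constant for the CO2 saturating model, s^-1.
#'
#' @return Long closures tibble (see [simulate_closure()]).
#' @export
simulate_closures <- function(campaign, times = NULL,
                              gases = c("ch4", "co2"), noise = TRUE,
                              kappa_co2 = 1 / 600) {
  stopifnot(inherits(campaign, "synthetic_campaign"))
  config <- campaign$config
  truth <- campaign$truth
  if (!is.null(times)) truth <- truth[truth$time %in% times, ]
  met <- campaign$met[match(truth$time, campaign$met$time), ]
  drift <- campaign$drift[match(truth$time, campaign$drift$time), ]
  set.seed(split_seed(campaign$seed, 15))

  dur <- config$closure_duration
  rate <- config$analyzer$sample_rate
  t_s <- seq(0, dur, by = 1 / rate)
  nt <- length(t_s)
  nr <- nrow(truth)
  out <- vector("list", length(gases))

  for (gi in seq_along(gases)) {
    g <- gases[gi]
    fluxes <- if (g == "ch4") truth$flux_true else truth$co2_true
    chamber_rows <- match(truth$chamber_id, config$chambers$chamber_id)
    ch_all <- config$chambers[chamber_rows, ]
    # vectorized inverse of the unit-conversion formula
    n_air <- (met$pressure_air * 1e3) * (ch_all$effective_volume * 1e-3) /
      (8.314 * (met$t_air + 273.15))
    conv <- gas_unit_to_molfrac(g) * n_air * gas_molar_mass(g) /
      ch_all$footprint_area * 3600 * 1e3      # flux per unit slope
    slope <- fluxes / conv
    c0 <- config$ambient[[g]] + drift[[g]] +
      stats::rnorm(nr, 0, config$ambient[[g]] * 0.001)
    tt <- rep(t_s, times = nr)
    slope_l <- rep(slope, each = nt)
    c0_l <- rep(c0, each = nt)
    conc <- if (g == "ch4") {
      c0_l + slope_l * tt
    } else {
      phi <- c0_l + slope_l / kappa_co2
      phi + (c0_l - phi) * exp(-kappa_co2 * tt)
    }
    if (noise) {
      conc <- conc + stats::rnorm(length(conc),
                                  0, config$analyzer$precision_1s[[g]])
    }
    out[[gi]] <- tibble::tibble(
      chamber_id = rep(truth$chamber_id, each = nt),
      time = rep(truth$time, each = nt),
      t_s = tt, gas = g, conc = conc,
      t_chamber = rep(met$t_air, each = nt),
      pressure_ambient = rep(met$pressure_air, each = nt),
      pressure_in = rep(truth$pressure_in, each = nt),
      pressure_out = rep(truth$pressure_out, each = nt),
      par_chamber = rep(
        ifelse(truth$transparency == "opaque", 0, met$par), each = nt)
    )
  }
  dplyr::bind_rows(out)
}

#' Hourly flux table from campaign ground truth
#'
#' Convenience accessor: the campaign's hourly true fluxes arranged as a
#' measurement-style long flux table (as produced by [compute_fluxes()]),
#' with met and soil drivers joined. Useful for exercising QC,
#' aggregation and driver-attribution stages at campaign scale without
#' simulating and refitting every closure trace.
#'
#' @param campaign A `synthetic_campaign`.
#' @param gases Gases to include (`"ch4"` rows carry `flux_true`,
#'   `"co2"` rows carry `co2_true`).
#'
#' @return Long tibble: `chamber_id`, `vegetation`, `transparency`,
#'   `time`, `doy`, `hour`, `gas`, `flux`, `er_true`, `pressure_in`,
#'   `pressure_out` plus met (`u_star`, `wind_speed`, `par`, `t_air`,
#'   `rain`) and soil columns.
#' @export
truth_flux_table <- function(campaign, gases = "ch4") {
  stopifnot(inherits(campaign, "synthetic_campaign"))
  base <- campaign$truth
  tabs <- lapply(gases, function(g) {
    tb <- base
    tb$gas <- g
    tb$flux <- if (g == "ch4") tb$flux_true else tb$co2_true
    tb
  })
  tab <- dplyr::bind_rows(tabs)
  tab <- dplyr::select(tab, -"flux_true", -"co2_true")
  tab <- dplyr::left_join(
    tab,
    campaign$met[, c("time", "u_star", "wind_speed", "par", "t_air",
                     "rain", "pressure_air")],
    by = "time"
  )
  dplyr::left_join(tab, campaign$soil, by = c("vegetation", "time"))
}
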