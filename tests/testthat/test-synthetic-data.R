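test_that("chamber layout invariants hold for the default campaign", {
  ch <- default_chambers()
  expect_equal(nrow(ch), 18)
  expect_equal(unname(table(ch$vegetation)), rep(6L, 3),
               ignore_attr = TRUE)
  counts <- table(ch$vegetation, ch$transparency)
  expect_true(all(counts == 3))
  expect_equal(ch$footprint_area, pi * (ch$collar_diameter / 2)^2)
  expect_true(all(ch$effective_volume >= 30 & ch$effective_volume <= 45))
  expect_error(chamber_spec(c("a", "a"), "lichen", "opaque"), "duplicated")
  expect_error(chamber_spec("a", "lichen", "opaque", collar_diameter = -1),
               "positive")
})

test_that("closure simulation inverts the flux conversion exactly", {
  ch <- one_chamber()
  # zero flux, no noise -> constant trace
  tr0 <- simulate_closure(0, "ch4", ch, noise = FALSE)
  expect_equal(length(unique(tr0$conc)), 1)
  # 3-min closure at 1 Hz -> 181 samples including t = 0
  expect_equal(nrow(tr0), 181)

  # noiseless linear closure: slope equals the hand unit-conversion
  # inverse and the flux round-trips exactly
  tr <- simulate_closure(-0.02, "ch4", ch, mode = "linear", noise = FALSE,
                         t_air = 15, pressure = 101.325)
  n_air <- 101.325e3 * 30e-3 / (8.314 * 288.15)
  slope_expected <- -0.02 / (1e-9 * n_air * 16.04 / 0.204 * 3600 * 1e3)
  expect_equal(diff(tr$conc[1:2]), slope_expected, tolerance = 1e-10)
  expect_equal(fit_linear(tr, "ch4")$slope0, slope_expected,
               tolerance = 1e-10)

  # saturating mode: exact single-exponential with matching initial slope
  tr_s <- simulate_closure(-0.02, "ch4", ch, mode = "saturating",
                           noise = FALSE, kappa = 1 / 600)
  fit <- fit_exponential(tr_s, "ch4", deadband_s = 0)
  expect_equal(fit$kappa, 1 / 600, tolerance = 1e-4)
  expect_equal(fit$slope0, slope_expected, tolerance = 1e-6)

  expect_error(simulate_closure(-0.02, "ch4", ch, mode = "saturating",
                                kappa = 0), "kappa")
  expect_error(simulate_closure(-0.02, "ch4", ch, duration = 0),
               "duration")
})

test_that("analyser noise sd matches the configured precision", {
  ch <- one_chamber()
  set.seed(7)
  # >= 1e4 samples across replicate closures; residual sd within 5%
  resid <- unlist(lapply(1:60, function(i) {
    tr <- simulate_closure(-0.02, "ch4", ch, noise = TRUE)
    truth <- simulate_closure(-0.02, "ch4", ch, noise = FALSE)
    tr$conc - truth$conc
  }))
  expect_gt(length(resid), 1e4)
  expect_equal(sd(resid), 1, tolerance = 0.05)
})

test_that("met generator covers the filter regime and photoperiod", {
  env <- simulate_met(season_config(), seed = 3)
  m <- env$met
  night <- (m$hour >= 23 | m$hour < 7)
  expect_gt(sum(night & m$u_star < 0.15 & m$wind_speed < 1.50), 0)
  # PAR below 100 umol m-2 s-1 between 23:00 and 06:00, despite 24-h
  # June daylight
  late_night <- m$hour >= 23 | m$hour <= 6
  expect_lt(max(m$par[late_night & m$doy < 182]), 100)
  expect_gt(max(m$par), 800)

  # determinism
  env2 <- simulate_met(season_config(), seed = 3)
  expect_identical(env, env2)
  expect_error(simulate_met(season_config(start_doy = 200, end_doy = 150)),
               "at least one day")
})

test_that("campaigns are seed-deterministic and internally consistent", {
  camp <- short_campaign(seed = 5, days = 6)
  camp2 <- short_campaign(seed = 5, days = 6)
  expect_identical(camp$truth, camp2$truth)
  expect_identical(camp$met, camp2$met)
  cl <- simulate_closures(camp, times = camp$met$time[1:4], gases = "ch4")
  cl2 <- simulate_closures(camp2, times = camp$met$time[1:4], gases = "ch4")
  expect_identical(cl, cl2)

  # every closure hour has a matching truth record
  expect_true(all(unique(cl$time) %in% camp$truth$time))
  # 18 chambers, 6 per vegetation type
  expect_equal(length(unique(camp$truth$chamber_id)), 18)

  expect_error(
    simulate_campaign(campaign_config(
      chambers = chamber_spec(c("x", "x"), "lichen", "opaque"))),
    "duplicated")
})

test_that("truth model respects sign rules per vegetation type", {
  cfg <- campaign_config(truth = truth_model(noise_sd = 0))
  camp <- simulate_campaign(cfg, seed = 3)
  tab <- truth_flux_table(camp)
  tus <- tab[tab$vegetation == "tussock", ]
  # noiseless tussock: emission only above the 30 cm wetness threshold
  expect_equal(sum(tus$flux > 0 & tus$wfps_30 <= 80), 0)
  expect_gt(sum(tus$flux > 0), 0)   # wet episodes do occur

  # default (noisy) model: lichen/shrub uptake almost surely
  noisy <- truth_flux_table(simulate_campaign(seed = 3))
  ls <- noisy[noisy$vegetation != "tussock", ]
  expect_gt(mean(ls$flux <= 0), 0.99)
})

test_that("configured diel peak migrates from afternoon to night", {
  camp <- simulate_campaign(seed = 11)
  dc <- diel_composite(truth_flux_table(camp), camp$chambers)
  for (v in c("lichen", "shrub")) {
    june <- dc[dc$season == "early" & dc$vegetation == v, ]
    aug <- dc[dc$season == "late" & dc$vegetation == v, ]
    peak_june <- june$hour[which.min(june$mean_flux)]
    peak_aug <- aug$hour[which.min(aug$mean_flux)]
    expect_true(peak_june >= 14 && peak_june <= 17)
    expect_true(peak_aug >= 22 || peak_aug <= 4)
  }
})

test_that("zero-noise zero-coupling campaign is recovered exactly", {
  cfg <- campaign_config(
    truth = truth_model(noise_sd = 0, moisture_sens = 0, temp_q10 = 1,
                        er_coupling = c(lichen = 0, shrub = 0, tussock = 0),
                        diel_amp = 0, tussock_emission_max = 0),
    pressure_fault_rate = 0
  )
  cfg$season <- season_config(start_doy = 180, end_doy = 181)
  camp <- simulate_campaign(cfg, seed = 2)
  tab <- truth_flux_table(camp)
  # constant per-chamber truth
  spread <- tapply(tab$flux, tab$chamber_id, function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))
  # closure refit recovers it exactly (noiseless linear closures)
  cl <- simulate_closures(camp, times = camp$met$time[1:2], gases = "ch4",
                          noise = FALSE)
  est <- compute_fluxes(cl, camp$chambers, gases = "ch4",
                        try_exponential = FALSE)
  truth <- camp$truth[match(paste(est$chamber_id, est$time),
                            paste(camp$truth$chamber_id, camp$truth$time)), ]
  expect_equal(est$flux, truth$flux_true, tolerance = 1e-9)
})
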