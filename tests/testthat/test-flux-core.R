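test_that("unit conversion matches the hand-derived ideal-gas value", {
  ch <- one_chamber(volume = 30)
  # independent dimensional-analysis oracle, computed from first
  # principles: n_air = P V / (R T); flux = slope * n_air * M / A * 3600e3
  n_air <- 101.325e3 * 30e-3 / (8.314 * 288.15)
  expected <- 0.01e-9 * n_air * 16.04 / 0.204 * 3600 * 1e3
  expect_equal(concentration_to_flux(0.01, "ch4", ch, 15, 101.325),
               expected, tolerance = 1e-12)
  expect_equal(expected, 3.6e-3, tolerance = 0.01)

  # zero slope, sign preservation, linearity in volume
  expect_identical(concentration_to_flux(0, "ch4", ch, 15, 101.325), 0)
  expect_lt(concentration_to_flux(-0.01, "ch4", ch, 15, 101.325), 0)
  ch2 <- one_chamber(volume = 60)
  expect_equal(concentration_to_flux(0.01, "ch4", ch2, 15, 101.325),
               2 * expected, tolerance = 1e-12)

  # gas-agnostic: same oracle with CO2 molar mass and ppm scaling
  exp_co2 <- 0.01e-6 * n_air * 44.01 / 0.204 * 3600 * 1e3
  expect_equal(concentration_to_flux(0.01, "co2", ch, 15, 101.325),
               exp_co2, tolerance = 1e-12)

  expect_error(concentration_to_flux(0.01, "ch4", ch, 15, -1), "pressure")
  expect_error(concentration_to_flux(0.01, "ch4", ch, -100, 101), "air temp")
})

test_that("linear fit recovers exact lines and flags short traces", {
  ch <- one_chamber()
  ser <- tibble::tibble(t_s = 0:180, gas = "ch4", conc = 2000 - 0.01 * (0:180))
  fit <- fit_linear(ser, "ch4")
  expect_equal(fit$slope0, -0.01, tolerance = 1e-12)
  expect_equal(fit$r2, 1)

  flat <- tibble::tibble(t_s = 0:180, gas = "ch4", conc = rep(2000, 181))
  fit_flat <- fit_linear(flat, "ch4")
  expect_equal(fit_flat$slope0, 0)
  expect_equal(fit_flat$r2, 0)

  short <- ser[1:40, ]  # 20 s dead-band leaves 21 points < 30
  fit_short <- fit_linear(short, "ch4")
  expect_false(fit_short$ok)
  expect_match(fit_short$flags, "insufficient_data")
})

test_that("noisy linear slope lands within its analytic OLS error", {
  # Monte-Carlo vs the closed-form OLS slope standard error
  set.seed(101)
  t_s <- 20:180
  sxx <- sum((t_s - mean(t_s))^2)
  se_analytic <- 1 / sqrt(sxx)  # sd 1 ppb noise
  slopes <- replicate(500, {
    ser <- tibble::tibble(t_s = 0:180, gas = "ch4",
                          conc = 2000 - 0.01 * (0:180) + rnorm(181))
    fit_linear(ser, "ch4")$slope0
  })
  expect_equal(mean(slopes), -0.01, tolerance = 3 * se_analytic / sqrt(500) /
                 0.01)
  expect_equal(sd(slopes), se_analytic, tolerance = 0.15)
})

test_that("exponential fit self-inverts and matches the linear limit", {
  ch <- one_chamber()
  # self-inversion: recover the generating parameters exactly
  kappa <- 1 / 600
  c0 <- 1950
  phi <- c0 - 60
  t_s <- 0:180
  ser <- tibble::tibble(t_s = t_s, gas = "ch4",
                        conc = phi + (c0 - phi) * exp(-kappa * t_s))
  fit <- fit_exponential(ser, "ch4", deadband_s = 0)
  expect_equal(fit$kappa, kappa, tolerance = 1e-6)
  expect_equal(fit$phi, phi, tolerance = 1e-6)
  expect_equal(fit$slope0, kappa * (phi - c0), tolerance = 1e-6)

  # kappa -> 0 limit: a barely saturating trace agrees with the linear
  # fit within 1%
  k_small <- 2e-5
  phi_s <- c0 - 0.01 / k_small
  lin_ser <- tibble::tibble(
    t_s = t_s, gas = "ch4",
    conc = phi_s + (c0 - phi_s) * exp(-k_small * t_s))
  lin <- fit_linear(lin_ser, "ch4", deadband_s = 0)
  exp_fit <- fit_exponential(lin_ser, "ch4", deadband_s = 0)
  expect_equal(exp_fit$slope0, lin$slope0, tolerance = 0.01)

  # too-short trace flagged
  expect_false(fit_exponential(ser[1:10, ], "ch4")$ok)
})

test_that("fit selection follows the per-gas rules and falls back", {
  ch <- one_chamber()
  # strongly curved CO2 accumulation -> exponential
  tr_co2 <- simulate_closure(200, "co2", ch, mode = "saturating",
                             noise = TRUE, seed = 5, kappa = 1 / 300)
  lin <- fit_linear(tr_co2, "co2")
  ex <- fit_exponential(tr_co2, "co2")
  expect_identical(select_fit(lin, ex, "co2", ch, 15, 101.325),
                   "exponential")

  # near-zero CH4 flux -> linear even if the exponential converges
  tr_ch4 <- simulate_closure(-0.02, "ch4", ch, mode = "saturating",
                             noise = TRUE, seed = 6)
  lin4 <- fit_linear(tr_ch4, "ch4")
  ex4 <- fit_exponential(tr_ch4, "ch4")
  expect_identical(select_fit(lin4, ex4, "ch4", ch, 15, 101.325), "linear")

  # failed exponential -> linear for both gases
  failed <- list(ok = FALSE, slope0 = NA_real_)
  expect_identical(select_fit(lin4, failed, "ch4", ch, 15, 101.325),
                   "linear")
  expect_identical(select_fit(lin, failed, "co2", ch, 15, 101.325),
                   "linear")
})

test_that("compute_flux round-trips simulated closures", {
  ch <- one_chamber()
  # noiseless linear: exact
  tr <- simulate_closure(-0.02, "ch4", ch, mode = "linear", noise = FALSE,
                         t_air = 15, pressure = 101.325)
  est <- compute_flux(tr, "ch4", ch, try_exponential = FALSE)
  expect_equal(est$flux, -0.02, tolerance = 1e-12)
  expect_identical(est$fit_type, "linear")

  # noiseless saturating CO2: exponential fit recovers the initial slope
  tr2 <- simulate_closure(300, "co2", ch, mode = "saturating",
                          noise = FALSE)
  est2 <- compute_flux(tr2, "co2", ch)
  expect_identical(est2$fit_type, "exponential")
  expect_equal(est2$flux, 300, tolerance = 5e-3)

  # 5-min manual closure goes down the same path
  tr5 <- simulate_closure(-0.05, "ch4", ch, duration = 300, noise = FALSE)
  expect_equal(nrow(tr5), 301)
  est5 <- compute_flux(tr5, "ch4", ch, try_exponential = FALSE)
  expect_equal(est5$flux, -0.05, tolerance = 1e-10)
})

test_that("NEE partitioning computes ER means and GPP differences", {
  chambers <- chamber_spec(
    c("o1", "o2", "o3", "t1"), "shrub",
    c("opaque", "opaque", "opaque", "transparent")
  )
  tm <- as.POSIXct("2021-07-01 12:00:00", tz = "UTC")
  tab <- tibble::tibble(
    chamber_id = c("o1", "o2", "o3", "t1"),
    time = tm, gas = "co2",
    flux = c(2, 3, 4, -2)   # ER mean 3; NEE -2 -> GPP -5
  )
  out <- partition_gpp(tab, chambers)
  expect_equal(out$er[out$chamber_id == "t1"], 3)
  expect_equal(out$gpp[out$chamber_id == "t1"], -5)
  expect_equal(out$er[out$chamber_id == "o1"], 2)
  expect_true(all(is.na(out$gpp[out$transparency == "opaque"])))

  # all-opaque table: no GPP anywhere
  out2 <- partition_gpp(tab[1:3, ], chambers[1:3, ])
  expect_true(all(is.na(out2$gpp)))

  # transparent hour without opaque partners: GPP missing, not zero
  tab3 <- tab[4, ]
  tab3$time <- tm + 3600
  out3 <- partition_gpp(rbind(tab, tab3), chambers)
  expect_true(is.na(out3$gpp[out3$time == tm + 3600]))
})

test_that("CO2 unit helper converts mg to umol consistently", {
  # 44.01 mg CO2 = 1 mmol -> 1000 umol per m2 per hour = 1000/3600 per s
  expect_equal(co2_mg_to_umol(44.01), 1000 / 3600, tolerance = 1e-12)
})
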