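drv_table <- function(seed = 1, chamber = "ch01") {
  camp <- simulate_campaign(seed = seed)
  tt <- truth_flux_table(camp)
  as.data.frame(tt[tt$chamber_id == chamber, ])
}

test_that("mtry tuning searches the OOB grid and handles degenerates", {
  set.seed(1)
  n <- 300
  tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  tab$y <- tab$x1 + 0.5 * tab$x2 + rnorm(n, 0, 0.2)
  m <- tune_candidates_per_split(tab, "y", c("x1", "x2", "x3"), seed = 4)
  expect_true(m %in% 1:3)
  # exhaustive check: the returned mtry attains the minimum OOB error of
  # the same seeded grid (oracle re-runs the grid independently)
  oob <- vapply(1:3, function(k) {
    set.seed(tundraflux:::split_seed(4, 100 + k))
    fit <- randomForest::randomForest(x = tab[, 1:3], y = tab$y, mtry = k,
                                      ntree = 100)
    fit$mse[100]
  }, numeric(1))
  expect_equal(m, which.min(oob))

  expect_identical(tune_candidates_per_split(tab, "y", "x1"), 1L)
  tab$const <- 1
  expect_warning(
    d <- tune_candidates_per_split(transform(tab, y = 0), "y",
                                   c("x1", "x2", "x3")),
    "zero-variance")
  expect_equal(d, 1L)
})

test_that("forest importance recovers the generative driver and noise", {
  set.seed(2)
  n <- 500
  tab <- data.frame(wfps = runif(n, 10, 60), t_soil = rnorm(n, 8, 3),
                    par = runif(n, 0, 1000))
  tab$flux <- -0.01 * exp(0.03 * (30 - tab$wfps)) + rnorm(n, 0, 0.002)
  rf <- fit_rf(tab, "flux", c("wfps", "t_soil", "par"), n_trees = 300,
               mtry = 1, pdp_points = 10, seed = 1)
  expect_identical(rf$importance$predictor[1], "wfps")
  expect_gt(rf$oob_variance_explained, 50)
  expect_true(all(rf$importance$inc_node_purity >= 0))
  expect_lte(rf$oob_variance_explained, 100)
  # partial dependence of the active driver is monotone decreasing in
  # uptake magnitude (flux rises towards 0 with wetter soil)
  pd <- rf$partial_dependence[rf$partial_dependence$predictor == "wfps", ]
  expect_gt(cor(pd$x, pd$yhat), 0.9)

  # pure-noise response: near-zero OOB variance explained
  tab$noise <- rnorm(n)
  rf0 <- fit_rf(tab, "noise", c("wfps", "t_soil", "par"), n_trees = 300,
                mtry = 1, pdp_points = 0, seed = 1)
  expect_lt(rf0$oob_variance_explained, 5)

  expect_error(fit_rf(tab, "flux", c("wfps", "missing_col")), "missing")
  expect_error(fit_rf(tab[1:10, ], "flux", "wfps"), "complete-case")
})

test_that("uptake-only subsetting and reproducibility hold", {
  tab <- drv_table(seed = 3)
  rf1 <- fit_rf(tab, "flux", c("wfps_surface", "t_soil_surface"),
                n_trees = 100, mtry = 1, pdp_points = 0, seed = 9,
                uptake_only = TRUE)
  rf2 <- fit_rf(tab, "flux", c("wfps_surface", "t_soil_surface"),
                n_trees = 100, mtry = 1, pdp_points = 0, seed = 9,
                uptake_only = TRUE)
  expect_identical(rf1$importance, rf2$importance)
  expect_equal(rf1$oob_variance_explained, rf2$oob_variance_explained)
})

test_that("per-chamber seasonal models rank the controlling driver", {
  tab <- drv_table(seed = 5)
  pc <- per_chamber_models(tab, min_rows = 50, n_trees = 150, seed = 2)
  expect_setequal(unique(pc$season), c("early", "peak", "late"))
  expect_true(all(pc$n >= 50))

  # moisture-controlled chamber: flux responds to WFPS only
  set.seed(3)
  tab1 <- tab
  tab1$flux <- -0.01 * exp(0.05 * (30 - tab1$wfps_surface)) +
    rnorm(nrow(tab1), 0, 0.001)
  pc1 <- per_chamber_models(tab1, n_trees = 150, seed = 2)
  expect_true(all(pc1$imp_wfps_surface > pc1$imp_t_soil_surface))

  # y = f(T) only: temperature dominates
  tab2 <- tab
  tab2$flux <- -0.01 * 2^((tab2$t_soil_surface - 8) / 10) +
    rnorm(nrow(tab2), 0, 0.001)
  pc2 <- per_chamber_models(tab2, n_trees = 150, seed = 2)
  expect_true(all(pc2$imp_t_soil_surface > pc2$imp_wfps_surface))

  # an empty cell is skipped with a warning
  tab3 <- tab[format(tab$time, "%m") != "07", ]
  tab3 <- rbind(tab3, transform(tab[1:10, ],
                                time = as.POSIXct("2021-07-01 00:00:00",
                                                  tz = "UTC")))
  expect_warning(pc3 <- per_chamber_models(tab3, n_trees = 100, seed = 2),
                 "skipped")
  expect_false("peak" %in% pc3$season)
})

test_that("identical predictor sets give exactly zero added variance", {
  tab <- drv_table(seed = 6)
  tab <- tab[season_label(tab$time) == "late", ]
  # degenerate: extra predictor already in the base set
  av <- added_variance(tab, base_predictors = c("t_soil_surface",
                                                "wfps_surface"),
                       extra = "wfps_surface", n_trees = 100, seed = 3)
  expect_equal(av$delta_ve, 0, tolerance = 1e-9)
})

test_that("coupled ER adds variance; shuffled ER does not", {
  tab <- drv_table(seed = 7, chamber = "ch10")  # shrub, transparent
  tab <- tab[season_label(tab$time) == "late", ]
  av1 <- added_variance(tab, extra = "er_true", n_trees = 400, seed = 4)
  set.seed(4)
  tab$er_shuffled <- sample(tab$er_true)
  av0 <- added_variance(tab, extra = "er_shuffled", n_trees = 400,
                        seed = 4)
  expect_gt(av1$delta_ve, av0$delta_ve)
  expect_gt(av1$delta_ve, 0)
  expect_gt(av0$delta_ve, -5)  # small negatives only, from resampling
})

test_that("timescale aggregation preserves the dominant driver", {
  # all chambers: the cross-vegetation moisture gradient dominates
  camp <- simulate_campaign(seed = 8)
  tt <- truth_flux_table(camp)
  tab <- as.data.frame(tt[seq(1, nrow(tt), by = 5), ])
  preds <- c("wfps_surface", "t_soil_surface")
  hourly <- aggregate_and_refit(tab, "hourly", predictors = preds,
                                n_trees = 150, mtry = 1, pdp_points = 0,
                                seed = 5)
  daily <- aggregate_and_refit(tab, "daily", predictors = preds,
                               n_trees = 150, mtry = 1, pdp_points = 0,
                               seed = 5, min_rows = 30)
  expect_identical(hourly$importance$predictor[1], "wfps_surface")
  expect_identical(daily$importance$predictor[1], "wfps_surface")
  expect_warning(
    aggregate_and_refit(tab[tab$doy < 178, ], "weekly", predictors = preds,
                        n_trees = 50, mtry = 1, pdp_points = 0,
                        min_rows = 2, seed = 5),
    "fewer than 8 weeks")
})

test_that("transfer entropy is non-negative, zero for constants, and
           detects a planted lag", {
  expect_equal(transfer_entropy(rep(1, 500), rnorm(500), lag = 1), 0)
  set.seed(6)
  x <- rnorm(3000)
  y <- c(rep(0, 3), x[1:(3000 - 3)]) + rnorm(3000, 0, 0.3)
  te_by_lag <- vapply(1:6, function(l) transfer_entropy(x, y, l),
                      numeric(1))
  expect_true(all(te_by_lag >= 0))
  expect_equal(which.max(te_by_lag), 3)

  scan <- te_lag_scan(x, y, max_lag = 6, n_surrogates = 100, seed = 2)
  expect_true(scan$significant[scan$lag == 3])
  expect_identical(which.max(scan$te), 3L)

  expect_error(te_lag_scan(x, y, max_lag = 0), "max_lag")
  expect_error(te_lag_scan(x[1:50], y[1:50], max_lag = 2), "too short")
})

test_that("independent series are rarely flagged significant", {
  set.seed(7)
  hits <- vapply(1:25, function(i) {
    x <- rnorm(600)
    y <- rnorm(600)
    scan <- te_lag_scan(x, y, max_lag = 1, n_surrogates = 60,
                        block_len = 24, seed = i)
    scan$significant[1]
  }, logical(1))
  expect_lt(mean(hits), 0.3)
})

test_that("flux-ER regression R2 tracks the imposed correlation", {
  cfg <- campaign_config(truth = truth_model(er_corr = 0.85))
  camp <- simulate_campaign(cfg, seed = 9)
  tab <- truth_flux_table(camp)
  reg <- uptake_er_regression(tab, camp$chambers)
  # opaque chambers only
  expect_equal(nrow(reg), 9)
  expect_true(all(reg$chamber_id %in%
                    camp$chambers$chamber_id[
                      camp$chambers$transparency == "opaque"]))
  # closed-form: population R2 = r^2 = 0.7225
  expect_true(all(abs(reg$r2 - 0.85^2) < 0.05))

  # decoupled generator: R2 near zero
  cfg0 <- campaign_config(truth = truth_model(er_corr = 0.001))
  camp0 <- simulate_campaign(cfg0, seed = 9)
  reg0 <- uptake_er_regression(truth_flux_table(camp0), camp0$chambers)
  expect_true(all(reg0$r2 < 0.05))

  # too few observations -> skipped
  small <- tab[tab$chamber_id == "ch01", ][1:5, ]
  expect_equal(nrow(uptake_er_regression(small, camp$chambers)), 0)
})
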