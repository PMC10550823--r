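#' Tune the number of candidate predictors per split
#'
#' Grid search over mtry (1..p) minimizing out-of-bag mean squared error
#' of a regression forest, mirroring the usual tuning step before fitting
#' the final model. Deterministic given the seed.
#'
#' @param table Data frame of complete cases.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names (>= 2).
#' @param seed Integer seed.
#' @param n_trees Trees per candidate evaluation (default 100; the final
#'   model uses its own, larger ensemble).
#' @return The OOB-optimal mtry (integer). A zero-variance response
#'   returns the conventional default `floor(p / 3)` with a warning.
#' @export
tune_candidates_per_split <- function(table, response, predictors, seed = 1,
                                      n_trees = 100) {
  stopifnot(length(predictors) >= 1)
  if (length(predictors) == 1) return(1L)
  y <- table[[response]]
  if (stats::var(y) == 0) {
    warning("zero-variance response; returning default floor(p/3)",
            call. = FALSE)
    return(max(1L, floor(length(predictors) / 3)))
  }
  x <- as.data.frame(table[, predictors, drop = FALSE])
  oob <- vapply(seq_along(predictors), function(m) {
    set.seed(split_seed(seed, 100 + m))
    fit <- randomForest::randomForest(x = x, y = y, mtry = m,
                                      ntree = n_trees)
    fit$mse[n_trees]
  }, numeric(1))
  which.min(oob)
}

#' Fit a random-forest flux model
#'
#' Regression forest of the flux response on environmental predictors,
#' reporting node-purity variable importance (total decrease in node sum
#' of squares per predictor, averaged over trees), out-of-bag variance
#' explained, and partial-dependence curves. Model 1 of the field
#' protocol uses six predictors (chamber PAR, met-station PAR, air
#' temperature, surface soil temperature, surface moisture, hour);
#' model 2 extends to the full depth-resolved predictor set. Highly
#' correlated predictors are retained (a collinearity warning is
#' emitted), since importance is interpreted jointly.
#'
#' @param table Data frame of hourly observations.
#' @param response Response column (default `"flux"`).
#' @param predictors Character vector of predictor columns.
#' @param n_trees Number of trees (default 500).
#' @param mtry Candidates per split; `NULL` (default) tunes it with
#'   [tune_candidates_per_split()].
#' @param nodesize Minimum terminal-node size (default 5, the
#'   randomForest regression default).
#' @param uptake_only Keep only negative (uptake) fluxes before fitting,
#'   as in the all-vegetation model (default `FALSE`).
#' @param min_rows Minimum complete-case rows (default 50).
#' @param pdp_points Grid size of partial-dependence curves (default 25;
#'   0 skips them).
#' @param seed Integer seed.
#' @param collinearity_warn Spearman correlation above which a predictor
#'   pair triggers a warning (default 0.7).
#'
#' @return An object of class `rf_result`: list with `importance` (tibble
#'   `predictor`, `inc_node_purity`, `rel_importance` summing to 1),
#'   `oob_variance_explained` (%), `partial_dependence` (tibble
#'   `predictor`, `x`, `yhat`), `mtry`, `n`, `seed` and the underlying
#'   `fit`.
#' @export
fit_rf <- function(table, response = "flux", predictors,
                   n_trees = 500, mtry = NULL, uptake_only = FALSE,
                   min_rows = 50, pdp_points = 25, seed = 1,
                   collinearity_warn = 0.7, nodesize = 5) {
  missing_cols <- setdiff(c(response, predictors), names(table))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tb <- table[, c(response, predictors)]
  tb <- tb[stats::complete.cases(tb), , drop = FALSE]
  if (uptake_only) tb <- tb[tb[[response]] < 0, , drop = FALSE]
  if (nrow(tb) < min_rows) {
    stop("fewer than ", min_rows, " complete-case rows", call. = FALSE)
  }
  if (length(predictors) > 1) {
    cm <- stats::cor(tb[, predictors], method = "spearman")
    diag(cm) <- 0
    if (any(abs(cm) > collinearity_warn)) {
      warning("highly correlated predictors retained (|Spearman| > ",
              collinearity_warn, ")", call. = FALSE)
    }
  }
  if (is.null(mtry)) {
    mtry <- tune_candidates_per_split(tb, response, predictors, seed = seed)
  }
  x <- as.data.frame(tb[, predictors, drop = FALSE])
  y <- tb[[response]]
  set.seed(split_seed(seed, 7))
  fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                    mtry = min(mtry, length(predictors)),
                                    nodesize = nodesize,
                                    importance = FALSE)
  imp <- randomForest::importance(fit, type = 2)  # IncNodePurity
  importance <- tibble::tibble(
    predictor = rownames(imp),
    inc_node_purity = as.numeric(imp[, 1]),
    rel_importance = as.numeric(imp[, 1]) / sum(imp[, 1])
  ) |> dplyr::arrange(dplyr::desc(.data$inc_node_purity))
  ve <- 100 * (1 - fit$mse[n_trees] / stats::var(y))

  pdp <- NULL
  if (pdp_points > 0) {
    pdp <- dplyr::bind_rows(lapply(predictors, function(p) {
      # do.call so partialPlot receives the predictor name by value
      pd <- do.call(randomForest::partialPlot,
                    list(fit, pred.data = x, x.var = p,
                         n.pt = pdp_points, plot = FALSE))
      tibble::tibble(predictor = p, x = pd$x, yhat = pd$y)
    }))
  }
  structure(
    list(importance = importance, oob_variance_explained = ve,
         partial_dependence = pdp, mtry = mtry, n = nrow(tb),
         seed = seed, fit = fit),
    class = "rf_result"
  )
}

#' @export
print.rf_result <- function(x, ...) {
  cat("<rf_result> n =", x$n, " mtry =", x$mtry,
      " OOB variance explained =",
      sprintf("%.1f%%", x$oob_variance_explained), "\n")
  print(x$importance, n = 6)
  invisible(x)
}

#' Per-chamber, per-month two-predictor models
#'
#' Fits a small random forest (default predictors: surface soil
#' temperature and surface WFPS) to each chamber x season-class cell,
#' controlling for microsite heterogeneity. Cells with too few rows are
#' skipped with a warning.
#'
#' @param table Hourly table with `chamber_id`, `time`, the response and
#'   predictor columns.
#' @param response Response column (default `"flux"`).
#' @param predictors Default `c("t_soil_surface", "wfps_surface")`.
#' @param min_rows Minimum rows per cell (default 50).
#' @param n_trees,seed Passed to [fit_rf()].
#' @return Tibble: `chamber_id`, `season`, one relative-importance column
#'   per predictor (`imp_<name>`), `variance_explained`, `n`.
#' @export
per_chamber_models <- function(table, response = "flux",
                               predictors = c("t_soil_surface",
                                              "wfps_surface"),
                               min_rows = 50, n_trees = 300, seed = 1) {
  table$season <- season_label(table$time)
  cells <- unique(table[table$season != "shoulder",
                        c("chamber_id", "season")])
  out <- vector("list", nrow(cells))
  skipped <- 0L
  for (i in seq_len(nrow(cells))) {
    cell <- table[table$chamber_id == cells$chamber_id[i] &
                    table$season == cells$season[i], ]
    cell <- cell[stats::complete.cases(cell[, c(response, predictors)]), ]
    if (nrow(cell) < min_rows) {
      skipped <- skipped + 1L
      next
    }
    rf <- fit_rf(cell, response, predictors, n_trees = n_trees,
                 mtry = 1, pdp_points = 0, min_rows = min_rows,
                 seed = split_seed(seed, i))
    row <- tibble::tibble(chamber_id = cells$chamber_id[i],
                          season = cells$season[i],
                          variance_explained = rf$oob_variance_explained,
                          n = rf$n)
    for (p in predictors) {
      row[[paste0("imp_", p)]] <-
        rf$importance$rel_importance[rf$importance$predictor == p]
    }
    out[[i]] <- row
  }
  if (skipped > 0) {
    warning(skipped, " chamber-month cell(s) below ", min_rows,
            " rows skipped", call. = FALSE)
  }
  dplyr::bind_rows(out)
}

#' Added explained variance from an extra predictor
#'
#' Difference in out-of-bag variance explained between a forest with the
#' base predictors plus one extra predictor (ecosystem respiration, by
#' default) and the base-only forest, fitted on identical rows with
#' paired seeds. Computed per chamber and season class, optionally also
#' split into daytime and night-time subsets.
#'
#' @param table Hourly table with `chamber_id`, `time`, response, base
#'   predictors and the extra predictor.
#' @param response Response column (default `"flux"`).
#' @param base_predictors Default `c("t_soil_surface", "wfps_surface")`.
#' @param extra Extra predictor column (default `"er_true"`).
#' @param day_night Also compute day/night splits? Night is 23:00-06:00
#'   (the hours with PAR below 100 umol m^-2 s^-1 at this latitude).
#' @param min_rows,n_trees,seed As in [per_chamber_models()].
#' @param mtry Candidates per split; `NULL` (default) uses every
#'   predictor as a split candidate in both models, so an uninformative
#'   extra predictor is out-competed rather than forced into splits.
#' @param nodesize Minimum terminal-node size (default 30; deeper trees
#'   overfit an uninformative extra predictor near the leaves and bias
#'   the comparison downwards).
#' @return Tibble: `chamber_id`, `season`, `period` (`"all"`, `"day"`,
#'   `"night"`), `ve_base`, `ve_extra`, `delta_ve`, `n`.
#' @export
added_variance <- function(table, response = "flux",
                           base_predictors = c("t_soil_surface",
                                               "wfps_surface"),
                           extra = "er_true", day_night = FALSE,
                           min_rows = 50, n_trees = 300, seed = 1,
                           mtry = NULL, nodesize = 30) {
  table$season <- season_label(table$time)
  table$hour <- as.integer(format(table$time, "%H"))
  periods <- if (day_night) c("all", "day", "night") else "all"
  cells <- unique(table[table$season != "shoulder",
                        c("chamber_id", "season")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    for (per in periods) {
      cell <- table[table$chamber_id == cells$chamber_id[i] &
                      table$season == cells$season[i], ]
      if (per == "day") cell <- cell[cell$hour >= 6 & cell$hour < 23, ]
      if (per == "night") cell <- cell[cell$hour >= 23 | cell$hour < 6, ]
      cols <- c(response, base_predictors, extra)
      cell <- cell[stats::complete.cases(cell[, cols]), ]
      if (nrow(cell) < min_rows) next
      s <- split_seed(seed, i * 10 + match(per, c("all", "day", "night")))
      m_base <- if (is.null(mtry)) length(base_predictors) else mtry
      m_ext <- if (is.null(mtry)) length(base_predictors) + 1 else mtry
      base <- fit_rf(cell, response, base_predictors, n_trees = n_trees,
                     mtry = m_base, pdp_points = 0, min_rows = min_rows,
                     seed = s, nodesize = nodesize)
      ext <- if (extra %in% base_predictors) base else {
        fit_rf(cell, response, c(base_predictors, extra),
               n_trees = n_trees, mtry = m_ext, pdp_points = 0,
               min_rows = min_rows, seed = s, nodesize = nodesize)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        chamber_id = cells$chamber_id[i], season = cells$season[i],
        period = per, ve_base = base$oob_variance_explained,
        ve_extra = ext$oob_variance_explained,
        delta_ve = ext$oob_variance_explained - base$oob_variance_explained,
        n = nrow(cell)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Refit the driver model at coarser timescales
#'
#' Mean-aggregates response and predictors to daily or weekly resolution
#' and refits the same forest, to check whether dominant predictors
#' change with timescale.
#'
#' @param table Hourly table with a `time` column.
#' @param scale `"hourly"`, `"daily"` or `"weekly"`.
#' @param response,predictors,... Passed to [fit_rf()].
#' @return An `rf_result`.
#' @export
aggregate_and_refit <- function(table, scale = c("hourly", "daily", "weekly"),
                                response = "flux", predictors, ...) {
  scale <- match.arg(scale)
  if (scale != "hourly") {
    unit <- if (scale == "daily") "day" else "week"
    table$.bin <- cut(table$time, breaks = unit)
    if (scale == "weekly" && length(unique(table$.bin)) < 8) {
      warning("fewer than 8 weeks at weekly scale", call. = FALSE)
    }
    grp_cols <- intersect(c("chamber_id", ".bin"), names(table))
    table <- table |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(c(response, predictors)),
                                     ~ mean(.x, na.rm = TRUE)),
                       .groups = "drop")
  }
  fit_rf(table, response, predictors, ...)
}
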