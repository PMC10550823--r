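#' Read a flux table from CSV
#'
#' Reads a long-format flux table with ISO-8601 timestamps. Unknown
#' columns are preserved. Rows whose timestamp cannot be parsed are
#' collected into an error report attached as the `"problems"` attribute
#' (and a warning), never silently dropped without notice.
#'
#' @param path CSV path.
#' @return A tibble; `time` parsed as POSIXct (UTC-stored local standard
#'   time). An empty file returns an empty tibble with a warning.
#' @export
read_flux_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          time = readr::col_character(),
                          .default = readr::col_guess()))
  if (nrow(tb) == 0) {
    warning("empty flux table: ", path, call. = FALSE)
    return(tb)
  }
  if ("time" %in% names(tb)) {
    parsed <- parse_iso_time(tb$time)
    bad <- which(is.na(parsed) & !is.na(tb$time))
    report <- tibble::tibble(row = bad,
                             value = as.character(tb$time[bad]),
                             problem = "unparseable timestamp")
    tb$time <- parsed
    if (length(bad)) {
      warning(length(bad), " row(s) with unparseable timestamps removed; ",
              "see attr(, 'problems')", call. = FALSE)
      tb <- tb[-bad, , drop = FALSE]
      attr(tb, "problems") <- report
    }
  }
  tb
}

# per-element ISO-8601 parsing over a list of accepted layouts
parse_iso_time <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in fmts) {
    idx <- which(is.na(out) & !is.na(x))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"))
  }
  out
}

#' Write a flux table to CSV
#'
#' Timestamps are serialized as ISO-8601 (`%Y-%m-%dT%H:%M:%SZ`), UTF-8.
#'
#' @param table Tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flux_table <- function(table, path) {
  tb <- table
  for (col in names(tb)) {
    if (inherits(tb[[col]], "POSIXct")) {
      tb[[col]] <- format(tb[[col]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    }
  }
  readr::write_csv(tb, path, progress = FALSE)
  invisible(path)
}

#' Write a synthetic campaign to a directory of CSV tables
#'
#' Writes `met.csv`, `soil.csv`, `truth.csv`, `chambers.csv` and a
#' `config.yml` echoing every generator parameter (including defaults),
#' plus `closures.csv` when closure traces are supplied.
#'
#' @param campaign A `synthetic_campaign`.
#' @param dir Output directory (created if needed).
#' @param closures Optional closures tibble from [simulate_closures()].
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir, closures = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_flux_table(campaign$met, file.path(dir, "met.csv"))
  write_flux_table(campaign$soil, file.path(dir, "soil.csv"))
  write_flux_table(campaign$truth, file.path(dir, "truth.csv"))
  write_flux_table(campaign$chambers, file.path(dir, "chambers.csv"))
  if (!is.null(closures)) {
    write_flux_table(closures, file.path(dir, "closures.csv"))
  }
  cfg <- campaign$config
  echo <- list(
    seed = campaign$seed,
    season = unclass(cfg$season),
    analyzer = lapply(unclass(cfg$analyzer), as.list),
    truth = lapply(unclass(cfg$truth), function(x) {
      if (is.null(x)) NULL else as.list(x)
    }),
    ambient = as.list(cfg$ambient),
    pressure_fault_rate = cfg$pressure_fault_rate,
    closure_duration = cfg$closure_duration
  )
  yaml::write_yaml(echo, file.path(dir, "config.yml"))
  invisible(dir)
}

#' Pipeline configuration
#'
#' End-to-end settings for [run_pipeline()]. Every knob has a default;
#' the effective configuration (defaults included) is echoed into the
#' output manifest.
#'
#' @param campaign A [campaign_config()]. The default demo campaign uses
#'   a short 14-day season so that closure-level refitting stays light;
#'   pass a full [season_config()] for season-scale runs.
#' @param seed Top-level seed for every stochastic stage.
#' @param gases Gases processed by the flux stage.
#' @param deadband_s,min_points Closure-fit settings (see [fit_linear()]).
#' @param qc A [qc_config()].
#' @param daytime_window Daytime sampling window for the bias estimator.
#' @param rf_predictors Predictors of the driver model.
#' @param te_max_lag,te_surrogates Transfer-entropy scan settings.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(campaign = campaign_config(
                              season = season_config(start_doy = 180,
                                                     end_doy = 193)),
                            seed = 1, gases = c("ch4", "co2"),
                            deadband_s = 20, min_points = 30,
                            qc = qc_config(), daytime_window = c(11, 15),
                            rf_predictors = c("par_chamber", "par",
                                              "t_air", "t_soil_surface",
                                              "wfps_surface", "hour"),
                            te_max_lag = 6, te_surrogates = 100) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> flux -> qc -> aggregate -> drivers -> stats on a
#' synthetic campaign and writes every product as CSV plus a JSON
#' manifest (row counts and the effective configuration). Rerunning with
#' the same config and seed reproduces byte-identical outputs. A failure
#' in any stage halts with a stage-labelled error.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the main in-memory products
#'   (`fluxes`, `qc`, `daily`, `diel`, `bias`, `rf`, `te`, `regression`,
#'   `stats`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  outputs <- list()
  emit <- function(table, file) {
    write_flux_table(table, file.path(out_dir, file))
    outputs[[file]] <<- nrow(table)
  }

  campaign <- stage("simulate", simulate_campaign(config$campaign,
                                                  config$seed))
  chambers <- campaign$chambers
  closures <- stage("simulate",
                    simulate_closures(campaign, gases = config$gases))

  fluxes <- stage("flux", compute_fluxes(
    closures, chambers, gases = config$gases,
    deadband_s = config$deadband_s, min_points = config$min_points,
    try_exponential = TRUE
  ))
  emit(fluxes, "fluxes.csv")

  qc_res <- stage("qc", apply_qc(fluxes, campaign$met, config$qc))
  emit(qc_res$fluxes, "fluxes_clean.csv")
  write_qc_summary(qc_res, file.path(out_dir, "qc_summary.json"))
  outputs[["qc_summary.json"]] <- nrow(qc_res$summary)

  ch4 <- dplyr::filter(qc_res$fluxes, .data$gas == "ch4")
  daily <- stage("aggregate", hourly_to_daily(ch4))
  emit(daily, "daily.csv")
  diel <- stage("aggregate", diel_composite(ch4, chambers))
  emit(diel, "diel.csv")
  bias <- stage("aggregate", suppressWarnings(
    daytime_bias(ch4, chambers, config$daytime_window)))
  emit(bias, "bias.csv")

  drv_tab <- stage("drivers", {
    tt <- truth_flux_table(campaign, gases = "ch4")
    tt$hour <- as.integer(format(tt$time, "%H"))
    dplyr::semi_join(tt, ch4, by = c("chamber_id", "time")) |>
      dplyr::mutate(par_chamber = ifelse(.data$transparency == "opaque",
                                         0, .data$par))
  })
  rf <- stage("drivers", fit_rf(drv_tab, "flux", config$rf_predictors,
                                n_trees = 300, mtry = 2, pdp_points = 15,
                                seed = config$seed))
  emit(rf$importance, "importance.csv")
  emit(rf$partial_dependence, "partial_dependence.csv")

  lichen_op <- chambers$chamber_id[chambers$vegetation == "lichen" &
                                     chambers$transparency == "opaque"][1]
  one <- drv_tab[drv_tab$chamber_id == lichen_op, ]
  one <- one[order(one$time), ]
  te <- stage("drivers", te_lag_scan(
    one$t_soil_surface, one$flux, max_lag = config$te_max_lag,
    n_surrogates = config$te_surrogates, seed = config$seed
  ))
  emit(tibble::as_tibble(te), "te_results.csv")

  reg <- stage("drivers", uptake_er_regression(drv_tab, chambers))
  emit(reg, "regression.csv")

  stats_tbl <- stage("stats", {
    by_day <- hourly_to_daily(ch4)
    by_day <- dplyr::left_join(
      by_day, chambers[, c("chamber_id", "vegetation")], by = "chamber_id")
    by_day <- by_day[is.finite(by_day$flux_daily), ]
    kd <- kw_dunn(by_day$flux_daily, by_day$vegetation)
    dplyr::mutate(kd$pairwise,
                  test = "kruskal_wallis_dunn",
                  h = kd$h, omnibus_p = kd$p_value,
                  letters1 = kd$letters[.data$group1],
                  letters2 = kd$letters[.data$group2])
  })
  emit(stats_tbl, "stats.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("tundraflux")),
    seed = config$seed,
    outputs = outputs,
    config = serialize_config(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fluxes = fluxes, qc = qc_res, daily = daily, diel = diel,
                 bias = bias, rf = rf, te = te, regression = reg,
                 stats = stats_tbl, manifest = manifest))
}

# flatten a pipeline_config into plain lists for the manifest, echoing
# every numeric default
serialize_config <- function(config) {
  as_plain <- function(x) {
    if (is.data.frame(x)) return(list(rows = nrow(x), cols = names(x)))
    if (is.list(x)) return(lapply(unclass(x), as_plain))
    if (is.function(x)) return(NULL)
    x
  }
  as_plain(config)
}
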