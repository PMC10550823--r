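#' Transfer entropy between two series at one lag
#'
#' Plug-in estimate of the transfer entropy from a source series x to a
#' target series y at a given lag: the mutual information between y_t and
#' x_(t-lag) conditional on the target's own immediate history y_(t-1)
#' (history length 1). Both series are discretized into equal-probability
#' (quantile) bins first. TE is non-negative by construction of the
#' plug-in estimator; tiny negative values from floating-point
#' cancellation are clipped at zero.
#'
#' @param x Source series (numeric).
#' @param y Target series, aligned with `x`.
#' @param lag Positive lag in sampling steps (hours, for hourly tables).
#' @param history Target history length (only 1 supported; argument kept
#'   for configurability of the interface).
#' @param bins Number of quantile bins (default 3).
#' @return TE in nats (a single non-negative number). Constant series
#'   give 0.
#' @export
transfer_entropy <- function(x, y, lag, history = 1, bins = 3) {
  stopifnot(length(x) == length(y), lag >= 1, history == 1)
  bx <- quantile_bin(x, bins)
  by <- quantile_bin(y, bins)
  te_binned(bx, by, lag, bins)
}

quantile_bin <- function(x, bins) {
  if (length(unique(x)) <= 1) return(rep(1L, length(x)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               na.rm = TRUE))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE, labels = FALSE))
}

# entropy (nats) of a discrete joint index vector
entropy_idx <- function(idx, levels) {
  p <- tabulate(idx, nbins = levels)
  p <- p[p > 0] / length(idx)
  -sum(p * log(p))
}

# TE from pre-binned series: H(y_t, y_{t-1}) + H(y_{t-1}, x_{t-lag})
#                          - H(y_{t-1}) - H(y_t, y_{t-1}, x_{t-lag})
te_binned <- function(bx, by, lag, bins) {
  n <- length(bx)
  span <- max(lag, 1)
  t_idx <- (span + 1):n
  if (length(t_idx) < 10) stop("series too short for this lag", call. = FALSE)
  yt <- by[t_idx]
  y1 <- by[t_idx - 1]
  xl <- bx[t_idx - lag]
  keep <- !is.na(yt) & !is.na(y1) & !is.na(xl)
  yt <- yt[keep]; y1 <- y1[keep]; xl <- xl[keep]
  h_yy <- entropy_idx(yt + bins * (y1 - 1), bins^2)
  h_yx <- entropy_idx(y1 + bins * (xl - 1), bins^2)
  h_y1 <- entropy_idx(y1, bins)
  h_yyx <- entropy_idx(yt + bins * (y1 - 1) + bins^2 * (xl - 1), bins^3)
  max(0, h_yy + h_yx - h_y1 - h_yyx)
}

# circular block shuffle: cut the (binned) source series into blocks and
# permute them, preserving within-block (incl. diel) structure
block_shuffle <- function(b, block_len) {
  n <- length(b)
  n_blocks <- ceiling(n / block_len)
  start <- sample.int(n, 1)
  rotated <- b[((start + seq_len(n) - 2) %% n) + 1]
  blocks <- split(rotated, rep(seq_len(n_blocks), each = block_len,
                               length.out = n))
  unlist(blocks[sample(n_blocks)], use.names = FALSE)[seq_len(n)]
}

#' Transfer-entropy lag scan with surrogate significance
#'
#' Computes TE from x to y over lags 1..`max_lag` and assesses
#' significance against a null ensemble of circularly block-shuffled
#' surrogates of the source series. The default block length of 24
#' samples (one day of hourly data) destroys the cross-coupling between
#' the series while retaining each day's diel autocorrelation, so diel
#' cycles alone do not produce spurious significance. A lag is flagged
#' significant when its TE exceeds the 95th percentile of its surrogate
#' distribution.
#'
#' @param x Source series.
#' @param y Target series, aligned with `x`.
#' @param max_lag Largest lag (>= 1) to scan.
#' @param n_surrogates Surrogates per lag (default 200).
#' @param bins Quantile bins (default 3).
#' @param block_len Surrogate block length in samples (default 24).
#' @param seed Integer seed; results are reproducible.
#' @return Object of class `te_result`: tibble with `lag`, `te`,
#'   `surrogate_mean`, `surrogate_q95`, `significant`.
#' @export
te_lag_scan <- function(x, y, max_lag, n_surrogates = 200, bins = 3,
                        block_len = 24, seed = 1) {
  if (max_lag < 1) stop("max_lag must be >= 1", call. = FALSE)
  n <- length(x)
  if (n < max_lag * 4 || n < 200) {
    stop("series too short for the requested lag scan", call. = FALSE)
  }
  set.seed(split_seed(seed, 21))
  bx <- quantile_bin(x, bins)
  by <- quantile_bin(y, bins)
  sur <- replicate(n_surrogates, block_shuffle(bx, block_len),
                   simplify = FALSE)
  res <- lapply(seq_len(max_lag), function(l) {
    te <- te_binned(bx, by, l, bins)
    te_null <- vapply(sur, te_binned, numeric(1), by = by, lag = l,
                      bins = bins)
    q95 <- stats::quantile(te_null, 0.95, names = FALSE)
    tibble::tibble(lag = l, te = te, surrogate_mean = mean(te_null),
                   surrogate_q95 = q95, significant = te > q95)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("te_result", class(out))
  out
}

#' Per-chamber regression of CH4 flux on ecosystem respiration
#'
#' Ordinary least squares of CH4 flux on ER for each opaque chamber
#' (opaque chambers measure ER directly), optionally split by light
#' period. Chambers with fewer than `min_n` paired observations are
#' skipped.
#'
#' @param flux_table Hourly tibble with `chamber_id`, CH4 `flux` and an
#'   ER column.
#' @param chambers Chamber spec tibble; only opaque chambers are used.
#' @param er_col Name of the ER column (default `"er_true"`).
#' @param by_light Also split into low-light (PAR < 100, requires a
#'   `par` column) and high-light subsets?
#' @param min_n Minimum observations per fit (default 10).
#' @return Tibble: `chamber_id`, `period`, `slope`, `intercept`, `r2`,
#'   `n`.
#' @export
uptake_er_regression <- function(flux_table, chambers, er_col = "er_true",
                                 by_light = FALSE, min_n = 10) {
  opaque <- chambers$chamber_id[chambers$transparency == "opaque"]
  tb <- flux_table[flux_table$chamber_id %in% opaque, ]
  periods <- if (by_light) c("all", "low_light", "high_light") else "all"
  out <- list()
  for (id in unique(tb$chamber_id)) {
    for (per in periods) {
      cell <- tb[tb$chamber_id == id, ]
      if (per == "low_light") cell <- cell[cell$par < 100, ]
      if (per == "high_light") cell <- cell[cell$par >= 100, ]
      cell <- cell[is.finite(cell$flux) & is.finite(cell[[er_col]]), ]
      if (nrow(cell) < min_n) next
      fit <- stats::lm(cell$flux ~ cell[[er_col]])
      out[[length(out) + 1]] <- tibble::tibble(
        chamber_id = id, period = per,
        slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        r2 = summary(fit)$r.squared, n = nrow(cell)
      )
    }
  }
  dplyr::bind_rows(out)
}
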