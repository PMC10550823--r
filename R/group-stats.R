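#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-tailed, as used for comparing flux distributions between
#' vegetation types across manual-chamber sites.
#'
#' @param a,b Numeric samples (each n >= 2 with finite variance).
#' @return Tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_a = mean(a), mean_b = mean(b),
    n_a = length(a), n_b = length(b)
  )
}

# Dunn's pairwise z statistics from pooled mid-ranks with tie correction
dunn_pairwise <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  dplyr::bind_rows(lapply(pairs, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / n_g[[p[1]]] + 1 / n_g[[p[2]]]))
    z <- (mean_rank[[p[1]]] - mean_rank[[p[2]]]) / se
    tibble::tibble(group1 = p[1], group2 = p[2], z = z,
                   p_value = 2 * stats::pnorm(-abs(z)))
  }))
}

#' Compact letter display from a pairwise p-value table
#'
#' Deterministic insert-and-absorb algorithm: groups that are *not*
#' significantly different at `alpha` share at least one letter.
#'
#' @param pairwise Tibble with `group1`, `group2` and an adjusted
#'   p-value column `p_adjusted`.
#' @param groups Character vector of all group names (fixes ordering).
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter codes per group.
#' @export
cld_letters <- function(pairwise, groups, alpha = 0.05) {
  k <- length(groups)
  same <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairwise))) {
    if (pairwise$p_adjusted[i] <= alpha) {
      g1 <- pairwise$group1[i]; g2 <- pairwise$group2[i]
      same[g1, g2] <- same[g2, g1] <- FALSE
    }
  }
  # each letter = one maximal clique of the "not significantly different"
  # graph, so any two groups sharing a letter are mutually non-different
  g_same <- igraph::graph_from_adjacency_matrix(same, mode = "undirected",
                                                diag = FALSE)
  cliques <- igraph::max_cliques(g_same)
  sets <- lapply(cliques, function(cl) sort(groups[as.integer(cl)]))
  sets <- sets[order(vapply(sets, function(s) match(s[1], groups),
                            integer(1)))]
  letters_out <- stats::setNames(rep("", k), groups)
  for (j in seq_along(sets)) {
    for (g in sets[[j]]) {
      letters_out[g] <- paste0(letters_out[g], letters[j])
    }
  }
  letters_out
}

# tie-corrected Kruskal-Wallis H from a rank vector and group labels
kw_h_stat <- function(r, groups) {
  n <- length(r)
  rs <- tapply(r, groups, sum)
  ng <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ng) - 3 * (n + 1)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h / corr else 0
}

# exact permutation p of the H statistic: enumerate every assignment of
# the pooled observations to groups of the observed sizes
kw_exact_p <- function(values, groups) {
  r <- rank(values)
  h_obs <- kw_h_stat(r, groups)
  sizes <- table(groups)
  k <- length(sizes)
  n <- length(r)
  hs <- numeric(0)
  recurse <- function(remaining, gi, assignment) {
    if (gi == k) {
      assignment[remaining] <- k
      hs[length(hs) + 1] <<- kw_h_stat(r, assignment)
      return(invisible())
    }
    picks <- utils::combn(remaining, sizes[gi], simplify = FALSE)
    for (p in picks) {
      assignment[p] <- gi
      recurse(setdiff(remaining, p), gi + 1, assignment)
    }
  }
  recurse(seq_len(n), 1, integer(n))
  mean(hs >= h_obs - 1e-12)
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' Rank-based omnibus H test (with tie correction) across groups,
#' followed by pairwise Dunn z tests on the pooled mid-ranks, step-down
#' p adjustment (Holm by default; Benjamini-Hochberg selectable) and a
#' compact letter display at `alpha`. For small pooled samples (n at or
#' below `exact_max`, default 10) the omnibus p-value is computed from
#' the exact permutation distribution of H rather than the chi-square
#' approximation, which is unreliable at those sizes.
#'
#' @param values Numeric observations.
#' @param groups Group labels (>= 2 groups, each n >= 2).
#' @param adjust P-adjustment method for the pairwise tests, passed to
#'   [stats::p.adjust()] (default `"holm"`).
#' @param alpha Level for the letter display (default 0.05).
#' @param exact_max Pooled sample size at or below which the exact
#'   permutation p is used (default 10; 0 disables).
#' @return List of class `kw_dunn`: `h`, `df`, `p_value` (omnibus),
#'   `p_method` (`"exact"` or `"chisq"`), `pairwise` (tibble with
#'   `group1`, `group2`, `z`, `p_value`, `p_adjusted`), `letters`
#'   (named character vector).
#' @export
kw_dunn <- function(values, groups, adjust = "holm", alpha = 0.05,
                    exact_max = 10) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs n >= 2", call. = FALSE)
  kw <- stats::kruskal.test(values, groups)
  if (length(values) <= exact_max) {
    p_val <- kw_exact_p(values, groups)
    p_method <- "exact"
  } else {
    p_val <- kw$p.value
    p_method <- "chisq"
  }
  pw <- dunn_pairwise(values, groups)
  pw$p_adjusted <- stats::p.adjust(pw$p_value, method = adjust)
  structure(
    list(h = unname(kw$statistic), df = unname(kw$parameter),
         p_value = p_val, p_method = p_method, pairwise = pw,
         letters = cld_letters(pw, levels(groups), alpha)),
    class = "kw_dunn"
  )
}

#' @export
print.kw_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f, df = %d, p = %.4g\n",
              x$h, x$df, x$p_value))
  print(x$pairwise)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}
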