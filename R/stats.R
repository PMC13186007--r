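# Group statistics: Kruskal-Wallis with Holm-adjusted Dunn post hoc
# pairwise tests, and Pearson/Spearman correlation matrices linking
# retinal to cortical metrics.

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected H, p from a
#' chi-square with k - 1 degrees of freedom) with the input checks used
#' throughout the package.
#'
#' @param groups List of >= 2 numeric samples, each non-empty, total
#'   n >= 3.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  .check_groups(groups)
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dunn's post hoc pairwise tests with Holm adjustment
#'
#' For each pair of groups the Dunn z statistic compares pooled mean ranks,
#' using midranks and the standard tie correction in the variance:
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/ni + 1/nj))` with
#' `T = sum(t^3 - t)` over tie groups. Two-sided normal p-values are
#' adjusted by Holm's step-down procedure across all pairs within the
#' analysis (the comparison family is the one marker-by-layer analysis,
#' not the whole study).
#'
#' @param groups List of >= 2 numeric samples (named or numbered).
#' @param p_adjust Adjustment method for [stats::p.adjust()], default
#'   `"holm"`.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return Data frame with one row per pair: `group_i`, `group_j`, `z`,
#'   `p_raw`, `p_adjusted`, `significant`.
#' @export
dunn_posthoc <- function(groups, p_adjust = "holm", alpha = 0.05) {
  .check_groups(groups)
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- as.character(seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)                       # midranks
  rbar <- tapply(r, g, mean)[names(groups)]
  n <- lengths(groups)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(k, 2L)
  z <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    (rbar[i] - rbar[j]) / sqrt(s2 * (1 / n[i] + 1 / n[j]))
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = p_adjust)
  data.frame(group_i = names(groups)[pairs[1L, ]],
             group_j = names(groups)[pairs[2L, ]],
             z = unname(z), p_raw = unname(p_raw),
             p_adjusted = unname(p_adj),
             significant = unname(p_adj < alpha))
}

#' Kruskal-Wallis global test plus Dunn post hoc
#'
#' @inheritParams dunn_posthoc
#' @return Object of class `group_test`: list with `H`, `df`, `p_global`,
#'   `pairwise` (the [dunn_posthoc()] table), `alpha`.
#' @export
kw_dunn <- function(groups, p_adjust = "holm", alpha = 0.05) {
  kw <- kruskal_wallis(groups)
  structure(list(H = kw$H, df = kw$df, p_global = kw$p,
                 pairwise = dunn_posthoc(groups, p_adjust, alpha),
                 alpha = alpha),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.3f, df = %d, p = %.4g\n",
              x$H, x$df, x$p_global))
  pw <- x$pairwise
  pw$stars <- significance_stars(pw$p_adjusted)
  print(pw, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Significance stars
#'
#' The figure convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Pearson and Spearman correlation matrix
#'
#' Correlates each retinal metric with each cortical metric using both
#' Pearson's r (linear association, t-based p) and Spearman's rho
#' (monotone association; rho is Pearson's r applied to midranks, its p
#' likewise t-based on the rank scale). Missing values are deleted
#' pairwise; pairs with fewer than 3 complete cases or zero variance are
#' reported with `NA` coefficients.
#'
#' @param table Data frame of region- or electrode-level metrics.
#' @param retinal_metrics,cortical_metrics Column names to cross.
#' @return Data frame of class `correlation_matrix` with one row per
#'   (retinal, cortical) pair: `retinal`, `cortical`, `n`, `r_pearson`,
#'   `p_pearson`, `rho_spearman`, `p_spearman`.
#' @export
correlation_matrix <- function(table, retinal_metrics,
                               cortical_metrics = c("best_threshold_uA",
                                                    "d_prime")) {
  miss <- setdiff(c(retinal_metrics, cortical_metrics), names(table))
  if (length(miss))
    stop("metric columns missing from table: ",
         paste(miss, collapse = ", "))
  rows <- expand.grid(retinal = retinal_metrics,
                      cortical = cortical_metrics,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    x <- table[[rows$retinal[i]]]; y <- table[[rows$cortical[i]]]
    keep <- stats::complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    res <- data.frame(retinal = rows$retinal[i],
                      cortical = rows$cortical[i], n = n,
                      r_pearson = NA_real_, p_pearson = NA_real_,
                      rho_spearman = NA_real_, p_spearman = NA_real_)
    if (n >= 3L && stats::var(x) > 0 && stats::var(y) > 0) {
      pe <- stats::cor.test(x, y, method = "pearson")
      res$r_pearson <- unname(pe$estimate)
      res$p_pearson <- pe$p.value
      sp <- stats::cor.test(rank(x), rank(y), method = "pearson")
      res$rho_spearman <- unname(sp$estimate)
      res$p_spearman <- sp$p.value
    }
    res
  }))
  class(out) <- c("correlation_matrix", class(out))
  out
}

#' @export
print.correlation_matrix <- function(x, ...) {
  y <- as.data.frame(x)
  y$pearson <- sprintf("%+.2f%s", y$r_pearson,
                       significance_stars(y$p_pearson))
  y$spearman <- sprintf("%+.2f%s", y$rho_spearman,
                        significance_stars(y$p_spearman))
  print(y[, c("retinal", "cortical", "n", "pearson", "spearman")],
        row.names = FALSE)
  invisible(x)
}

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  if (any(lengths(groups) == 0L)) stop("empty group")
  if (sum(lengths(groups)) < 3L) stop("need at least 3 observations")
  invisible(TRUE)
}
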