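# Noise metrics and the statistical comparison toolkit: the DM
# (distance-from-running-median CV) abundance-independent noise measure,
# rank-sum tests, Benjamini-Hochberg adjustment, chi-square
# goodness-of-fit and box-plot summaries.

#' Abundance-independent noise (DM)
#'
#' The CV of a gene is confounded with its mean abundance (low-abundance
#' genes are noisier), so the abundance-independent measure is the
#' residual of log CV from a running median taken over genes of similar
#' abundance: genes are ranked by mean, the median of `log(cv)` is
#' computed in a centred rank window of `window` genes (shrunk
#' symmetrically at the edges), and `dm = log(cv) - running median`.
#'
#' @param records Tibble with numeric `mean` and `cv` columns (> 0; rows
#'   violating this are dropped with a warning). Other columns pass
#'   through.
#' @param window Rank-window size (default 50; the realised window is the
#'   odd `2 * floor(window / 2) + 1` in the interior).
#' @param log_base Logarithm base for `dm` (default 10).
#' @return The input tibble (valid rows only) with a `dm` column added,
#'   in the original row order.
#' @export
compute_dm <- function(records, window = 50, log_base = 10) {
  if (!is.data.frame(records) ||
      !all(c("mean", "cv") %in% names(records))) {
    abort("`records` must have `mean` and `cv` columns.")
  }
  bad <- !is.finite(records$mean) | !is.finite(records$cv) |
    records$mean <= 0 | records$cv <= 0
  if (any(bad)) {
    warn(sprintf("%d record(s) with non-positive mean or cv excluded from DM.",
                 sum(bad)))
    records <- records[!bad, , drop = FALSE]
  }
  n <- nrow(records)
  if (n < window) {
    abort(sprintf("DM needs at least `window` = %d genes (got %d).",
                  window, n))
  }
  ord <- order(records$mean)
  lcv <- log(records$cv[ord], base = log_base)
  h <- floor(window / 2)
  run_med <- vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)
    stats::median(lcv[(i - hi):(i + hi)])
  }, numeric(1))
  dm <- numeric(n)
  dm[ord] <- lcv - run_med
  out <- tibble::as_tibble(records)
  out$dm <- dm
  out
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided comparison of two samples: exact enumeration for small
#' untied samples, normal approximation with tie correction otherwise
#' (the `stats::wilcox.test` switching rule at n = 50).
#'
#' @param x,y Numeric samples (each with at least one value).
#' @param exact Force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   branch.
#' @return A one-row tibble: `statistic` (Mann-Whitney W), `p_value`,
#'   `method`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))
rank_sum_test <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty.")
  if (!is.numeric(x) || !is.numeric(y)) abort("samples must be numeric.")
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact)
  )
  tibble(statistic = unname(res$statistic),
         p_value = res$p.value,
         method = res$method)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || !length(pvalues)) {
    abort("`pvalues` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Chi-square goodness-of-fit
#'
#' Compares observed category counts with expected counts:
#' `sum((O - E)^2 / E)` on `k - 1` degrees of freedom.
#'
#' @param observed,expected Equal-length count vectors; `expected` must be
#'   strictly positive and there must be at least two categories.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chisq_enrichment(c(10, 0), c(5, 5))
chisq_enrichment <- function(observed, expected) {
  if (!is.numeric(observed) || !is.numeric(expected) ||
      length(observed) != length(expected)) {
    abort("`observed` and `expected` must be numeric vectors of equal length.")
  }
  if (length(observed) < 2L) {
    abort("at least two categories are required (df would be zero).")
  }
  if (any(expected <= 0)) abort("expected counts must be strictly positive.")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  tibble(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Box-plot summary with outlier flags
#'
#' Quartiles by linear interpolation of order statistics
#' (`stats::quantile` type 7); values beyond 1.5 x IQR of the quartiles
#' are flagged as outliers but never removed from the data (removal is a
#' display-only convention).
#'
#' @param values Numeric sample with at least one value.
#' @return A one-row tibble: `n`, `median`, `q1`, `q3`, `iqr`,
#'   `lower_fence`, `upper_fence`, `n_outliers`, and `outliers` (a
#'   list-column with the flagged values).
#' @export
#' @examples
#' boxplot_summary(c(1, 1, 1, 100))
boxplot_summary <- function(values) {
  if (!is.numeric(values) || !length(values)) {
    abort("`values` must be a non-empty numeric vector.")
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  out <- values[values < lo | values > hi]
  tibble(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
         iqr = iqr, lower_fence = lo, upper_fence = hi,
         n_outliers = length(out), outliers = list(out))
}
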