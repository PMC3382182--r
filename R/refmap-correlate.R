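#' Spearman correlation between chromosome GC and coverage
#'
#' Tie-aware Spearman rho (Pearson correlation of average ranks) with
#' one-sided and two-sided p-values from the t-approximation with
#' `n - 2` degrees of freedom. The one-sided value (positive association)
#' is the headline statistic.
#'
#' @param gc numeric vector (e.g. per-chromosome GC).
#' @param coverage numeric vector of the same length (e.g. per-chromosome
#'   coverage fraction).
#' @return a `CorrelationResult`: list with `rho`, `p_one_sided`,
#'   `p_two_sided`, `n`.
#' @export
gc_coverage_correlation <- function(gc, coverage) {
  assert_that(length(gc) == length(coverage), "input lengths differ")
  n <- length(gc)
  assert_that(n >= 3, "need at least 3 observations")
  assert_that(stats::sd(gc) > 0 && stats::sd(coverage) > 0,
              "zero variance: correlation undefined")
  rho <- stats::cor(rank(gc), rank(coverage))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  structure(list(rho = rho,
                 p_one_sided = stats::pt(tstat, n - 2, lower.tail = FALSE),
                 p_two_sided = 2 * stats::pt(abs(tstat), n - 2,
                                             lower.tail = FALSE),
                 n = n),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d, one-sided p = %.4g)\n",
              x$rho, x$n, x$p_one_sided))
  invisible(x)
}
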