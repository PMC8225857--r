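## Package-side implementations of the classical tests used for motif
## comparisons.  Written out from the textbook definitions so the test suite
## can check them against the independent implementations in base R.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Computes the exact two-sided p-value by summing, over the hypergeometric
#' support of the table, the probabilities of all tables at most as probable
#' as the observed one (the standard "sum of small p" definition, with a
#' 1 + 1e-7 relative tolerance against ties, as in base R).
#'
#' @param tab 2x2 integer matrix of counts.
#' @return list with `p_value` and `odds_ratio` (sample odds ratio).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != floor(tab)))
    stopf("fisher_exact_2x2() needs a 2x2 table of non-negative integers")
  x <- tab[1, 1]
  m <- sum(tab[1, ])          # row-1 total
  k <- sum(tab[, 1])          # column-1 total
  n2 <- sum(tab[2, ])
  support <- max(0, k - n2):min(k, m)
  d <- dhyper(support, m, n2, k)
  p <- sum(d[d <= d[support == x] * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p_value = min(1, p), odds_ratio = or)
}

#' Unpaired two-sided Student's t test (pooled variance)
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
student_t_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stopf("each group needs >= 2 observations")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- if (se == 0) 0 else (mean(a) - mean(b)) / se
  list(statistic = tstat, df = df, p_value = 2 * pt(-abs(tstat), df))
}

## Shared constructor for the comparison result record.
motif_comparison <- function(statistic, p_value, test, n_comparisons,
                             extra = list()) {
  assert_scalar_int(n_comparisons, "n_comparisons", lower = 1)
  out <- c(list(statistic = statistic,
                p_value = p_value,
                p_bonferroni = min(1, p_value * n_comparisons),
                test = test,
                n_comparisons = as.integer(n_comparisons)),
           extra)
  class(out) <- "motif_comparison"
  out
}

#' @export
print.motif_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.3g, Bonferroni p = %.3g (m = %d)\n",
              x$test, x$statistic, x$p_value, x$p_bonferroni,
              x$n_comparisons))
  invisible(x)
}
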