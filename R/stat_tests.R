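#' @importFrom rlang .data
NULL

new_test_result <- function(method, statistic = NA_real_, df = NA_real_, p_value) {
  tibble::tibble(method = method,
                 statistic = as.numeric(statistic),
                 df = as.numeric(df),
                 p_value = as.numeric(p_value))
}

#' Build a 2x2 contingency matrix
#'
#' Rows are groups, columns are outcome yes/no.
#'
#' @param a,b First row (yes, no).
#' @param c,d Second row (yes, no).
#' @return A 2x2 integer matrix.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  m <- matrix(as.integer(c(a, c, b, d)), nrow = 2)
  if (any(m < 0)) rlang::abort("contingency counts must be non-negative")
  m
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sidedness follows the minimum-likelihood rule: the p-value is the sum
#' of hypergeometric probabilities of all tables with the same margins whose
#' probability does not exceed that of the observed table (the convention of
#' [stats::fisher.test()]).
#'
#' @param table A 2x2 matrix of non-negative counts (rows = groups,
#'   columns = outcome yes/no); see [contingency_2x2()].
#' @return A one-row tibble with columns `method`, `statistic` (`NA` for an
#'   exact test), `df` (`NA`) and `p_value`.
#' @examples
#' fisher_exact_two_sided(contingency_2x2(7, 3, 1, 9))
#' @export
fisher_exact_two_sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) rlang::abort("table must be 2x2")
  if (any(table < 0)) rlang::abort("counts must be non-negative")
  if (sum(table) == 0) rlang::abort("all-zero table: Fisher's exact test undefined")
  p <- stats::fisher.test(table, alternative = "two.sided")$p.value
  new_test_result("Fisher's exact test (two-sided)", p_value = min(p, 1))
}

#' Chi-squared goodness-of-fit test
#'
#' Pearson statistic \eqn{\sum (O-E)^2/E} with `df = k - 1`; the expected
#' vector is rescaled internally to the observed total.
#'
#' @param observed Vector of non-negative counts, length >= 2.
#' @param expected Vector of positive expected values (any scale).
#' @return A one-row tibble (`method`, `statistic`, `df`, `p_value`).
#' @examples
#' chisq_goodness_of_fit(c(10, 10, 40), c(1, 1, 1))
#' @export
chisq_goodness_of_fit <- function(observed, expected) {
  if (length(observed) < 2 || length(observed) != length(expected)) {
    rlang::abort("observed and expected must have equal length >= 2")
  }
  if (any(expected <= 0)) rlang::abort("expected values must all be > 0")
  if (any(observed < 0)) rlang::abort("observed counts must be non-negative")
  ht <- suppressWarnings(stats::chisq.test(observed, p = expected / sum(expected)))
  new_test_result("Chi-squared goodness-of-fit",
                  statistic = ht$statistic, df = ht$parameter, p_value = ht$p.value)
}

#' Chi-squared test of independence
#'
#' Pearson statistic without continuity correction on an r x c table,
#' `df = (r-1)(c-1)`.
#'
#' @param table An r x c matrix of non-negative counts, r, c >= 2.
#' @return A one-row tibble (`method`, `statistic`, `df`, `p_value`).
#' @examples
#' chisq_independence(matrix(c(10, 20, 20, 10), nrow = 2))
#' @export
chisq_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) rlang::abort("table must be at least 2x2")
  if (any(table < 0)) rlang::abort("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    rlang::abort("table has a zero margin; chi-squared test undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  new_test_result("Chi-squared test of independence",
                  statistic = ht$statistic, df = ht$parameter, p_value = ht$p.value)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses the exact permutation null when the combined sample size is at most
#' 12 and there are no ties; otherwise the normal approximation with midranks,
#' tie-corrected variance and continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @return A one-row tibble; `statistic` is the Mann-Whitney U of `x`.
#' @examples
#' wilcoxon_rank_sum_two_sided(c(1, 2, 3), c(4, 5, 6))
#' @export
wilcoxon_rank_sum_two_sided <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) rlang::abort("both samples must be non-empty")
  exact <- (length(x) + length(y) <= 12) && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  new_test_result(
    if (exact) "Wilcoxon rank-sum (exact)" else "Wilcoxon rank-sum (normal approximation)",
    statistic = ht$statistic, p_value = ht$p.value
  )
}
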