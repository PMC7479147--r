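#' Two-sided rank-sum (Mann-Whitney) test
#'
#' Pairwise group comparison by the Mann-Whitney U statistic with midrank
#' ties. The p-value is exact (full enumeration of arrangements) for small
#' samples without ties (`n1 * n2 <= exact_max_products`), otherwise the
#' normal approximation with tie and continuity corrections is used —
#' matching the behaviour of standard statistics software.
#'
#' @param a,b numeric samples (>= 1 observation each).
#' @param exact_max_products switch to the approximation when `n1 * n2`
#'   exceeds this (default 400).
#' @param continuity apply the continuity correction in the approximate
#'   case.
#' @return a `comparison_result`: list with `statistic` (U for sample `a`),
#'   `p_value`, `method`, `n` (group sizes).
#' @export
rank_sum_test <- function(a, b, exact_max_products = 400, continuity = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1 || length(b) < 1) stop("both samples need >= 1 observation")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) * length(b) <= exact_max_products
  wt <- stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = exact, correct = continuity)
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = "rank_sum_two_sided",
                 exact = exact, n = c(length(a), length(b))),
            class = "comparison_result")
}

#' Two-sided exact test of proportions (Fisher)
#'
#' Exact two-sided comparison of two proportions from a 2x2 count table,
#' with the two-sided p-value defined by the probability-mass criterion:
#' the sum of hypergeometric probabilities of all tables (same margins) no
#' more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts with all row and
#'   column margins nonzero.
#' @return a `comparison_result` with `statistic` (the conditional
#'   odds-ratio estimate), `p_value`, `method`, `n` (row totals).
#' @export
exact_proportions_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin: proportions comparison undefined")
  }
  ft <- stats::fisher.test(table, alternative = "two.sided")
  structure(list(statistic = unname(ft$estimate), p_value = ft$p.value,
                 method = "exact_proportions_two_sided",
                 n = rowSums(table)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Descriptive summary of a sample
#'
#' Mean, standard deviation (n - 1 denominator), standard error of the mean,
#' and sample size; SD and SEM are `NA` with `defined = FALSE` for n = 1.
#'
#' @param x numeric sample.
#' @return list with `mean`, `sd`, `sem`, `n`, `defined`.
#' @export
summarize_sample <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 1) stop("empty sample")
  if (n == 1) {
    return(list(mean = x, sd = NA_real_, sem = NA_real_, n = 1L,
                defined = FALSE))
  }
  s <- stats::sd(x)
  list(mean = mean(x), sd = s, sem = s / sqrt(n), n = n, defined = TRUE)
}
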