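#' @title Cohort-level statistics
#' @name cohort_stats
#' @description
#' Group comparisons (Mann-Whitney, Welch t, one-way ANOVA), correlations
#' (Pearson, Spearman) and contingency tests used for sidedness contrasts,
#' cluster contrasts, mutation x cluster tables and VEGFA-cytotoxicity
#' couplings. Thin, contract-enforcing wrappers around base R's tested
#' implementations; each returns a uniform result record.
NULL

comparison_result <- function(test_name, group_sizes, statistic, p_value, direction) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(test_name = test_name, group_sizes = group_sizes,
                 statistic = unname(statistic), p_value = min(unname(p_value), 1),
                 direction = direction),
            class = "ComparisonResult")
}

#' Two-group comparison
#'
#' Mann-Whitney uses the exact distribution when both groups have n <= 20
#' and the data are tie-free, and the normal approximation with continuity
#' correction otherwise. The t-test is the Welch unequal-variance variant.
#' `direction` is the sign of mean(group 1) - mean(group 2) in the order of
#' the label levels.
#'
#' @param values numeric vector.
#' @param labels vector with exactly 2 distinct non-missing values.
#' @param test `"mann_whitney"` or `"t_test"`.
#' @return `ComparisonResult` list: `test_name`, `group_sizes`, `statistic`,
#'   `p_value` (two-sided), `direction`.
#' @export
compare_groups <- function(values, labels, test = c("mann_whitney", "t_test")) {
  test <- match.arg(test)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("compare_groups requires exactly 2 groups")
  g1 <- values[labels == levels(labels)[1L]]
  g2 <- values[labels == levels(labels)[2L]]
  if (length(g1) == 0L || length(g2) == 0L) stop("a group is empty")
  direction <- sign(mean(g1) - mean(g2))
  if (test == "mann_whitney") {
    exact <- length(g1) <= 20L && length(g2) <= 20L && !anyDuplicated(c(g1, g2))
    ht <- suppressWarnings(stats::wilcox.test(g1, g2, exact = exact, correct = TRUE))
    comparison_result("mann_whitney", c(length(g1), length(g2)),
                      ht$statistic, ht$p.value, direction)
  } else {
    if (length(g1) < 2L || length(g2) < 2L) stop("t-test needs >= 2 per group")
    ht <- stats::t.test(g1, g2)  # Welch by default
    comparison_result("t_test_welch", c(length(g1), length(g2)),
                      ht$statistic, ht$p.value, direction)
  }
}

#' One-way ANOVA over k >= 3 groups
#'
#' Classic equal-variance F test with (k - 1, n - k) degrees of freedom.
#'
#' @param values numeric vector.
#' @param labels grouping with >= 3 levels, >= 2 observations each.
#' @return `ComparisonResult` with the F statistic; `direction` is `NA`.
#' @export
anova_oneway <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 3L) stop("one-way ANOVA here requires >= 3 groups")
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("group(s) with < 2 observations: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  ht <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  comparison_result("anova_oneway", as.integer(sizes), ht$statistic, ht$p.value, NA_real_)
}

#' Pearson or Spearman correlation with two-sided p
#'
#' p-values via the t transform with n - 2 df (Spearman: the same transform
#' applied to the rank correlation, the large-sample convention).
#'
#' @param x,y equal-length numeric vectors, n >= 3, finite.
#' @param method `"pearson"` or `"spearman"`.
#' @return list `r`, `p_value`, `n`, `method` (class `CorrelationResult`).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("correlation needs n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p_value = p, n = n, method = method),
            class = "CorrelationResult")
}

#' Test independence in an R x C contingency table
#'
#' Chi-square test with (R-1)(C-1) df; for a 2 x 2 table with any expected
#' count below 5 the Fisher exact test is used instead.
#'
#' @param tab non-negative integer matrix/table with positive margins.
#' @return `ComparisonResult`; `statistic` is `NA` for Fisher exact.
#' @export
contingency_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("table must hold non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("zero margin in table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == c(2L, 2L)) && any(expected < 5)) {
    ht <- stats::fisher.test(tab)
    comparison_result("fisher_exact", as.integer(rowSums(tab)), NA_real_,
                      ht$p.value, NA_real_)
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    comparison_result("chi_square", as.integer(rowSums(tab)), ht$statistic,
                      ht$p.value, NA_real_)
  }
}

#' Benjamini-Hochberg adjustment (off by default in reports)
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
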