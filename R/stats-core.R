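#' Pearson correlation test
#'
#' Sample Pearson correlation with a two-sided p-value from the
#' t-distribution with n - 2 degrees of freedom. A constant input is
#' not an error: the pair is flagged untestable so that genome-wide
#' screens never abort on a degenerate row.
#'
#' @param x,y Numeric vectors of equal length (>= 3 for a p-value).
#' @return A one-row tibble: `estimate`, `p_value`, `n`, `method`,
#'   `testable`.
#' @export
#' @examples
#' cor_test_pearson(1:10, (1:10)^2)
cor_test_pearson <- function(x, y) {
  cor_test_impl(x, y, method = "pearson")
}

#' Spearman rank correlation test
#'
#' Spearman's rho computed as the Pearson correlation of mid-ranks
#' (average ranks for ties), with the same t-distribution p-value as
#' [cor_test_pearson()] applied to the ranks.
#'
#' @inheritParams cor_test_pearson
#' @return A one-row tibble: `estimate`, `p_value`, `n`, `method`,
#'   `testable`.
#' @export
#' @examples
#' cor_test_spearman(c(1, 2, 2, 3), c(10, 20, 20, 40))
cor_test_spearman <- function(x, y) {
  cor_test_impl(x, y, method = "spearman")
}

cor_test_impl <- function(x, y, method) {
  if (length(x) != length(y)) abort("x and y must have the same length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  not_testable <- tibble::tibble(
    estimate = NA_real_, p_value = NA_real_, n = n,
    method = method, testable = FALSE
  )
  if (n < 3) {
    return(not_testable)
  }
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(not_testable)
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(
    estimate = unname(ct$estimate), p_value = ct$p.value, n = n,
    method = method, testable = TRUE
  )
}

#' Welch two-sample t test
#'
#' Unequal-variance t test (Satterthwaite degrees of freedom),
#' two-sided.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4))
welch_t <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("welch_t needs at least 2 finite observations per group")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    # zero pooled variance: identical groups give p = 1, else p = 0
    identical_groups <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble::tibble(
      statistic = if (identical_groups) 0 else Inf * sign(mean(a) - mean(b)),
      df = NA_real_,
      p_value = if (identical_groups) 1 else 0,
      method = "welch_t"
    ))
  }
  tt <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  tibble::tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, method = "welch_t"
  )
}

#' Mann-Whitney U test
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) test. The p-value is
#' exact (full enumeration of the rank-sum null) when the smaller
#' group has at most `exact_max` observations and there are no ties;
#' otherwise the normal approximation with continuity and tie
#' correction is used.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @param exact_max Largest min-group size for which the exact null
#'   distribution is used (default 8).
#' @return A one-row tibble: `statistic` (U for the first group),
#'   `p_value`, `method`, `exact`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(a, b, exact_max = 8) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 1 || length(b) < 1) {
    abort("mann_whitney needs non-empty groups")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && min(length(a), length(b)) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(a, b,
      alternative = "two.sided",
      exact = use_exact, correct = TRUE
    )
  )
  tibble::tibble(
    statistic = unname(wt$statistic), p_value = min(wt$p.value, 1),
    method = "mann_whitney_u", exact = use_exact
  )
}

#' Pearson chi-square test of independence
#'
#' Chi-square test on an observed contingency table, statistic
#' sum((O - E)^2 / E), no continuity correction, p-value from the
#' chi-square distribution with (r - 1)(c - 1) degrees of freedom.
#'
#' @param tab Non-negative integer matrix with at least 2 rows and 2
#'   columns and no zero marginal total.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_sq_independence(matrix(c(20, 5, 5, 20), 2))
chi_sq_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("contingency table needs at least 2 rows and 2 columns")
  }
  if (any(tab < 0)) abort("contingency table must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate contingency table: zero row or column total")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: adjusted p for the i-th
#' smallest raw p is min over j >= i of (m / j) p_(j), capped at 1,
#' returned in the original order. `NA` entries (untestable rows) are
#' preserved and do not count toward m.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\] (NA allowed).
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05))
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}
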