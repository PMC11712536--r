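#' Chi-squared goodness-of-fit test against expected proportions
#'
#' Pearson goodness-of-fit of observed category counts against expected
#' proportions (e.g. SV element-class counts against the genome-wide bp
#' share of each element). The statistic is `sum((O - E)^2 / E)` with
#' `E = N * p`, `df = k - 1`, upper-tail p-value.
#'
#' @param observed Named or unnamed vector of counts.
#' @param expected_proportions Proportions summing to 1.
#' @return A list of class `sv_gof`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected`, `low_expected_warning` (any expected cell
#'   below 5).
#' @export
chisq_gof <- function(observed, expected_proportions) {
  stopifnot(length(observed) == length(expected_proportions),
            sum(observed) > 0)
  if (abs(sum(expected_proportions) - 1) > 1e-9)
    stop("expected proportions must sum to 1")
  if (any(expected_proportions <= 0))
    stop("zero expected cell; pool categories before testing")
  ht <- suppressWarnings(
    stats::chisq.test(observed, p = expected_proportions))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 observed = observed,
                 expected = unname(ht$expected),
                 low_expected_warning = any(ht$expected < 5)),
            class = "sv_gof")
}

#' Chi-squared test of homogeneity on a contingency table
#'
#' Pearson test on an r x c table (e.g. SV-type distributions across
#' samples) with `E_ij = row_i * col_j / N`, `df = (r-1)(c-1)`. No
#' continuity correction is applied, so the 2 x 2 statistic equals the
#' closed form `N(ad - bc)^2 / (r1 r2 c1 c2)`.
#'
#' @param table An r x c matrix of counts (r, c >= 2; no zero margins).
#' @return A list of class `sv_gof` (as [chisq_gof()]).
#' @export
chisq_homogeneity <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("degenerate table: need at least 2 rows and 2 columns")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 observed = table,
                 expected = ht$expected,
                 low_expected_warning = any(ht$expected < 5)),
            class = "sv_gof")
}

#' @export
print.sv_gof <- function(x, ...) {
  cat(sprintf("<sv_gof> X-squared = %.4f, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$low_expected_warning) " (expected cell < 5)" else ""))
  invisible(x)
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two length samples (e.g. INDEL
#' sizes between treatments). The reported `u_statistic` is the
#' Mann-Whitney U of the first sample (`stats::wilcox.test`'s `W`);
#' the p-value uses the normal approximation with tie-corrected
#' variance and 0.5 continuity correction.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return A list of class `sv_ranktest`: `u_statistic`, `p_value`,
#'   `n1`, `n2`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both samples")
    return(structure(list(u_statistic = n1 * n2 / 2, p_value = 1,
                          n1 = n1, n2 = n2), class = "sv_ranktest"))
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  structure(list(u_statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value), n1 = n1, n2 = n2),
            class = "sv_ranktest")
}

#' @export
print.sv_ranktest <- function(x, ...) {
  cat(sprintf("<sv_ranktest> U = %g (n1 = %d, n2 = %d), p = %.4g\n",
              x$u_statistic, x$n1, x$n2, x$p_value))
  invisible(x)
}
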