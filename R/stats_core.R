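# Shared statistical primitives. Every downstream stage (selectivity,
# metric scan, correlations, behavior) calls into these rather than
# re-deriving test statistics locally, so conventions (tie correction,
# no Yates correction, eta^2 definition) are fixed in one place.

#' Construct a test-result record
#'
#' Uniform container returned by the hypothesis tests in this package.
#'
#' @param statistic test statistic value.
#' @param df degrees of freedom (may be length 2 for F tests).
#' @param p p value in `[0, 1]`.
#' @param eta_sq effect size (eta squared) where applicable, else `NA`.
#' @param degenerate logical; `TRUE` when the input was degenerate (e.g.
#'   zero total sum of squares) and the p value was set by convention.
#' @param method short label for the test.
#' @return An object of class `"pfc_test"` (a named list).
#' @keywords internal
test_result <- function(statistic, df, p, eta_sq = NA_real_,
                        degenerate = FALSE, method = "") {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  structure(
    list(statistic = statistic, df = df, p = p, eta_sq = eta_sq,
         degenerate = degenerate, method = method),
    class = "pfc_test"
  )
}

#' @export
print.pfc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g",
              x$method, x$statistic, paste(x$df, collapse = ", "), x$p))
  if (!is.na(x$eta_sq)) cat(sprintf(", eta^2 = %.4f", x$eta_sq))
  if (isTRUE(x$degenerate)) cat("  [degenerate]")
  cat("\n")
  invisible(x)
}

#' Kruskal-Wallis one-way analysis of variance by ranks
#'
#' Rank-based test for a location difference among k independent groups,
#' with the standard tie correction and a chi-square approximation for the
#' p value (k - 1 degrees of freedom).  This is the selectivity test applied
#' to per-trial firing rates across the four cue quadrants.
#'
#' @param groups list of numeric vectors, one per group; each must have
#'   at least 2 observations.
#' @return A [test_result()] with the H statistic.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9), c(10, 11, 12)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("kruskal_wallis() needs a list of >= 2 groups")
  n_i <- lengths(groups)
  if (any(n_i < 2))
    stop("kruskal_wallis(): every group must have n >= 2 (got n = ",
         paste(n_i, collapse = ","), ")")
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) stop("kruskal_wallis(): NA values in input")
  n <- length(x)
  r <- rank(x)
  g <- rep.int(seq_along(groups), n_i)
  rank_sums <- vapply(split(r, g), sum, numeric(1))
  h <- 12 / (n * (n + 1)) * sum(rank_sums^2 / n_i) - 3 * (n + 1)
  # tie correction
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  df <- length(groups) - 1
  if (correction <= 0) {
    # all observations identical: H is 0 by convention, p = 1
    return(test_result(0, df, 1, degenerate = TRUE, method = "Kruskal-Wallis"))
  }
  h <- h / correction
  test_result(h, df, stats::pchisq(h, df, lower.tail = FALSE),
              method = "Kruskal-Wallis")
}

#' One-way fixed-effects ANOVA with eta squared
#'
#' Classical one-way ANOVA; the effect size eta^2 = SS_between / SS_total is
#' always reported because the dose scans in this pipeline run at sample
#' sizes where p values alone are not interpretable.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return A [test_result()] with the F statistic, `df = c(df1, df2)`,
#'   p value and `eta_sq`.  A zero total sum of squares is flagged
#'   degenerate with `p = 1`, `eta_sq = 0`.
#' @examples
#' one_way_anova(list(c(1, 2), c(3, 4)))  # eta^2 = 0.8
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("one_way_anova() needs a list of >= 2 groups")
  n_i <- lengths(groups)
  if (any(n_i < 2))
    stop("one_way_anova(): every group must have n >= 2")
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) stop("one_way_anova(): NA values in input")
  k <- length(groups)
  n <- length(x)
  grand <- mean(x)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(n_i * (means - grand)^2)
  ss_total <- sum((x - grand)^2)
  df1 <- k - 1
  df2 <- n - k
  if (ss_total <= 0) {
    return(test_result(NA_real_, c(df1, df2), 1, eta_sq = 0,
                       degenerate = TRUE, method = "one-way ANOVA"))
  }
  ss_within <- ss_total - ss_between
  eta_sq <- ss_between / ss_total
  if (ss_within <= 0) {
    # distinct means, no within-group variance: F diverges
    return(test_result(Inf, c(df1, df2), 0, eta_sq = eta_sq,
                       degenerate = TRUE, method = "one-way ANOVA"))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  test_result(f, c(df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE),
              eta_sq = eta_sq, method = "one-way ANOVA")
}

#' Bonferroni significance flags
#'
#' Flags `p_i < alpha / m` with `m = length(p_values)` (strict inequality;
#' a p value exactly at the corrected threshold is not significant).
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @param alpha family-wise error rate, default 0.05.
#' @param m number of tests in the family; defaults to `length(p_values)`
#'   but can be set larger when some tests of a declared family were
#'   skipped (the family size, not the attempted count, defines the
#'   correction).
#' @return logical vector of significance flags.
#' @export
bonferroni <- function(p_values, alpha = 0.05, m = length(p_values)) {
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)), m >= 1)
  !is.na(p_values) & p_values < alpha / m
}

#' Pearson chi-square test for two proportions
#'
#' 2x2 Pearson chi-square (1 df), without continuity correction, as used
#' for hit-rate and error-rate comparisons between a dose pool and its
#' flanking placebo pool.  Also returns the standard error of each sample
#' proportion, `sqrt(p * (1 - p) / n)`.
#'
#' @param hits_a,n_a successes and trials in pool A.
#' @param hits_b,n_b successes and trials in pool B.
#' @return A [test_result()] with extra fields `p_a`, `p_b`, `se_a`, `se_b`.
#' @examples
#' chi_square_proportions(80, 100, 60, 100)  # chi^2 = 9.5238
#' @export
chi_square_proportions <- function(hits_a, n_a, hits_b, n_b) {
  stopifnot(n_a >= 1, n_b >= 1, hits_a >= 0, hits_b >= 0,
            hits_a <= n_a, hits_b <= n_b)
  p_a <- hits_a / n_a
  p_b <- hits_b / n_b
  pool <- (hits_a + hits_b) / (n_a + n_b)
  out <- if (pool <= 0 || pool >= 1) {
    # zero-margin table: no information about a difference
    test_result(0, 1, 1, degenerate = TRUE, method = "chi-square (2x2)")
  } else {
    chi2 <- (p_a - p_b)^2 / (pool * (1 - pool) * (1 / n_a + 1 / n_b))
    test_result(chi2, 1, stats::pchisq(chi2, 1, lower.tail = FALSE),
                method = "chi-square (2x2)")
  }
  out$p_a <- p_a
  out$p_b <- p_b
  out$se_a <- sqrt(p_a * (1 - p_a) / n_a)
  out$se_b <- sqrt(p_b * (1 - p_b) / n_b)
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length, n >= 3, both with nonzero
#'   variance.  Zero variance yields `NA` with a warning (the caller is
#'   expected to exclude and log the pair).
#' @return correlation coefficient in `[-1, 1]`, or `NA_real_`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("pearson_r(): n must be >= 3")
  if (anyNA(x) || anyNA(y)) stop("pearson_r(): NA values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("pearson_r(): zero-variance input, correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}
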