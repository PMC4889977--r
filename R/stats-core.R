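# Shared statistical primitives. Exact tests follow the "probability mass
# <= observed" two-sided convention (with the customary 1 + 1e-7 relative
# guard against floating-point ties), matching standard implementations.

test_result <- function(statistic, p_value, df = NA_real_, exact = FALSE,
                        estimate = NA_real_, conf_int = c(NA_real_, NA_real_),
                        method = "") {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 df = unname(df), exact = exact, estimate = unname(estimate),
                 conf_int = unname(conf_int), method = method),
            class = "sexqtl_test")
}

#' @export
print.sexqtl_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$method, x$statistic,
              x$p_value, if (x$exact) " (exact)" else ""))
  if (!is.na(x$estimate)) cat(sprintf("  estimate = %.4g [%.4g, %.4g]\n",
                                      x$estimate, x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

REL_TOL <- 1 + 1e-7

#' Fisher's exact test for a 2x2 table
#'
#' The p-value is computed by direct hypergeometric enumeration. Two-sided:
#' sum of the probabilities of all tables (with the observed margins) whose
#' probability does not exceed the observed table's. One-sided alternatives
#' refer to the odds ratio of the first row ("greater" = first cell enriched).
#' The conditional-MLE odds ratio and CI are taken from [stats::fisher.test].
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param sided `"two"`, `"greater"` or `"less"`.
#' @param or_ci also compute the conditional-MLE odds ratio and its CI
#'   (slower; delegates to [stats::fisher.test]).
#' @return A `sexqtl_test` with the exact p-value and sample odds ratio
#'   (conditional MLE when `or_ci = TRUE`).
#' @export
fisher_exact <- function(table, sided = c("two", "greater", "less"),
                         or_ci = FALSE) {
  sided <- match.arg(sided)
  table <- as.matrix(table)
  stopifnot(dim(table) == c(2, 2))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  a <- table[1, 1]
  m <- sum(table[1, ]); n <- sum(table[2, ]); k <- sum(table[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  p <- switch(sided,
    two = sum(dens[dens <= dens[support == a] * REL_TOL]),
    greater = sum(dens[support >= a]),
    less = sum(dens[support <= a]))
  p <- min(1, p)
  if (or_ci) {
    alt <- switch(sided, two = "two.sided", greater = "greater", less = "less")
    ft <- stats::fisher.test(table, alternative = alt)
    est <- unname(ft$estimate); ci <- as.numeric(ft$conf.int)
  } else {
    est <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
    ci <- c(NA_real_, NA_real_)
  }
  test_result(statistic = a, p_value = p, exact = TRUE, estimate = est,
              conf_int = ci, method = "Fisher's exact test")
}

#' Exact binomial test
#'
#' Two-sided p sums the probabilities of all outcomes no more likely than the
#' observed count.
#'
#' @param k successes, `n` trials, `p0` null probability.
#' @param sided `"two"`, `"greater"` or `"less"`.
#' @return A `sexqtl_test`; estimate is the sample proportion.
#' @export
binomial_exact <- function(k, n, p0 = 0.5, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  stopifnot(k >= 0, k <= n)
  dens <- stats::dbinom(0:n, n, p0)
  p <- switch(sided,
    two = sum(dens[dens <= dens[k + 1] * REL_TOL]),
    greater = sum(dens[(0:n) >= k]),
    less = sum(dens[(0:n) <= k]))
  test_result(statistic = k, p_value = min(1, p), exact = TRUE,
              estimate = k / n, method = "exact binomial test")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Uses the exact null distribution when `length(x) + length(y) <= 30` and
#' there are no ties; otherwise the normal approximation with midranks and
#' tie-corrected variance (no continuity correction, so the approximate
#' two-sided p is label-swap invariant).
#'
#' @param x,y numeric samples. `sided` as in [fisher_exact] ("greater" means
#'   `x` tends larger).
#' @return A `sexqtl_test` (statistic W = rank-sum based Mann-Whitney U of x).
#' @export
wilcoxon_rank_sum <- function(x, y, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical; p = 1")
    return(test_result(statistic = length(x) * length(y) / 2, p_value = 1,
                       exact = TRUE, method = "Wilcoxon rank-sum test"))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 30) && !ties
  alt <- switch(sided, two = "two.sided", greater = "greater", less = "less")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alt,
                                            exact = exact, correct = FALSE))
  test_result(statistic = wt$statistic, p_value = wt$p.value, exact = exact,
              method = "Wilcoxon rank-sum test")
}

#' Benjamini-Hochberg q-values and Bonferroni adjustment
#'
#' @param pvals numeric vector of p-values.
#' @return `bh_fdr`: step-up q-values (monotone, `>=` raw p).
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  stats::p.adjust(pvals, method = "BH")
}

#' @rdname bh_fdr
#' @param m number of tests (defaults to `length(pvals)`).
#' @return `bonferroni`: `min(1, m * p)`.
#' @export
bonferroni <- function(pvals, m = length(pvals)) pmin(1, m * pvals)

#' Welch's two-sample t-test
#' @param x,y numeric samples (each of size >= 3).
#' @return A `sexqtl_test`; estimate = mean(x) - mean(y).
#' @export
welch_t <- function(x, y) {
  if (length(x) < 3 || length(y) < 3) stop("group sizes must be >= 3")
  tt <- stats::t.test(x, y, var.equal = FALSE)
  test_result(statistic = tt$statistic, p_value = tt$p.value,
              df = tt$parameter, estimate = diff(rev(tt$estimate)),
              conf_int = as.numeric(tt$conf.int), method = "Welch's t-test")
}

#' Shapiro-Wilk normality test
#' @param x numeric sample, 3 <= n <= 5000.
#' @return A `sexqtl_test`.
#' @export
shapiro_wilk <- function(x) {
  st <- stats::shapiro.test(x)
  test_result(statistic = st$statistic, p_value = st$p.value,
              method = "Shapiro-Wilk normality test")
}

#' Brown-Forsythe (median-centered Levene) variance-equality test
#'
#' One-way ANOVA on the absolute deviations from the group medians.
#'
#' @param x,y numeric samples.
#' @return A `sexqtl_test` (F statistic, df = c(1, n - 2)).
#' @export
brown_forsythe <- function(x, y) {
  zx <- abs(x - stats::median(x))
  zy <- abs(y - stats::median(y))
  nx <- length(zx); ny <- length(zy); n <- nx + ny
  mz <- mean(c(zx, zy))
  ssb <- nx * (mean(zx) - mz)^2 + ny * (mean(zy) - mz)^2
  ssw <- sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2)
  if (ssw == 0) {
    f <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    f <- (ssb / 1) / (ssw / (n - 2))
    p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  }
  test_result(statistic = f, p_value = p, df = n - 2,
              method = "Brown-Forsythe test")
}

#' F-test for equality of variances
#' @param x,y numeric samples.
#' @return A `sexqtl_test`; estimate = var(x)/var(y).
#' @export
f_var_test <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vy == 0) {
    if (vx == 0) return(test_result(1, 1, method = "F variance test"))
    return(test_result(Inf, 0, estimate = Inf, method = "F variance test"))
  }
  ft <- stats::var.test(x, y)
  test_result(statistic = ft$statistic, p_value = ft$p.value,
              estimate = ft$estimate, conf_int = as.numeric(ft$conf.int),
              method = "F variance test")
}

#' Pearson chi-squared test for a 2 x k table
#'
#' No continuity correction is applied (uniform behaviour across k).
#'
#' @param table 2 x k matrix of counts.
#' @return A `sexqtl_test`.
#' @export
chisq_2xk <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("degenerate margin in chi-squared table; p = 1 by convention")
    return(test_result(0, 1, method = "chi-squared test"))
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  test_result(statistic = ct$statistic, p_value = ct$p.value,
              df = ct$parameter, method = "chi-squared test")
}
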