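# Sex-specific differential mean expression and differential variance (DV).
#
# Three DV strategies:
#   A_F        - F-test on every gene.
#   B_gated    - Shapiro-Wilk normality gate, then F-test (normal) or
#                Brown-Forsythe (non-normal).
#   C_residual - quantile-normalize each gene to N(0,1), regress out sex,
#                then gate-and-test the regression residuals, separating
#                genuine DV from DV induced by a mean (DE) difference.

#' Sex-balanced subsample
#'
#' Returns the indices of all samples of the minority sex plus a seeded
#' uniform subsample of the majority sex of equal size, so variance
#' comparisons are not confounded by unequal group sizes.
#'
#' @param sex 0/1 vector.
#' @param seed integer seed for the subsample draw.
#' @return Integer sample indices (sorted).
#' @export
match_subsample <- function(sex, seed) {
  im <- which(sex == 0); if_ <- which(sex == 1)
  if (!length(im) || !length(if_)) stop("both sexes must be present")
  if (length(im) == length(if_)) return(seq_along(sex))
  minor <- if (length(im) < length(if_)) im else if_
  major <- if (length(im) < length(if_)) if_ else im
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  sort(c(minor, sample(major, length(minor))))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Rank-based quantile normalization to N(0,1)
#'
#' Maps ranks r (midranks for ties) to `qnorm((r - 0.5)/n)`.
#'
#' @param values finite numeric vector, length >= 2, not constant.
#' @return Normalized values in the input order.
#' @export
quantile_normalize_to_normal <- function(values) {
  if (length(values) < 2) stop("need at least two values")
  if (!all(is.finite(values))) stop("values must be finite")
  if (stats::var(values) == 0) stop("constant vector cannot be quantile-normalized")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.5) / length(values))
}

dv_one <- function(x_m, x_f, strategy, alpha_normality, gate_scope) {
  branch <- "F"
  if (strategy == "A_F") {
    tr <- f_var_test(x_f, x_m)
  } else {
    pooled <- c(x_m - mean(x_m), x_f - mean(x_f))
    normal <- if (gate_scope == "pooled") {
      shapiro_wilk(pooled)$p_value >= alpha_normality
    } else {
      shapiro_wilk(x_m)$p_value >= alpha_normality &&
        shapiro_wilk(x_f)$p_value >= alpha_normality
    }
    if (normal) tr <- f_var_test(x_f, x_m)
    else { branch <- "BF"; tr <- brown_forsythe(x_f, x_m) }
  }
  c(statistic = tr$statistic, p = tr$p_value,
    branch = branch,
    direction = if (stats::var(x_f) >= stats::var(x_m)) "female" else "male")
}

#' Differential expression variance between the sexes
#'
#' @param expr an [expression_matrix] of kind `"residuals"`.
#' @param sex optional 0/1 vector (defaults to `expr$samples$sex`).
#' @param strategy `"A_F"`, `"B_gated"` or `"C_residual"` (see file header).
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @param gate_scope apply the gate to the pooled within-sex-centered values
#'   (`"pooled"`, default) or require normality in each sex (`"per_sex"`).
#' @param qn for strategy C: `"none"` (default) regresses sex out of the
#'   residual-scale values directly and relies on the normality gate (with
#'   the Brown-Forsythe fallback) for robustness; `"gene"` first maps each
#'   gene's values onto normal scores. The `"gene"` pretransform makes the
#'   two sex groups a without-replacement partition of one fixed score set,
#'   which pins the pooled variance and renders the parametric F reference
#'   strongly conservative — it is kept for literal reproduction of
#'   rank-normalized pipelines, not as the default.
#' @return data.frame per gene: strategy, branch (`F`/`BF`), statistic, p,
#'   BH q, direction (higher-variance sex).
#' @export
test_dv <- function(expr, sex = expr$samples$sex,
                    strategy = c("B_gated", "A_F", "C_residual"),
                    alpha_normality = 0.05,
                    gate_scope = c("pooled", "per_sex"),
                    qn = c("none", "gene")) {
  strategy <- match.arg(strategy)
  gate_scope <- match.arg(gate_scope)
  qn <- match.arg(qn)
  if (expr$kind != "residuals") stop("DV testing expects residual-scale expression")
  if (min(sum(sex == 0), sum(sex == 1)) < 3) stop("need >= 3 samples per sex")
  if (sum(sex == 0) != sum(sex == 1))
    message("note: unequal sex groups; consider match_subsample()")
  vals <- expr$values
  res <- t(apply(vals, 1, function(y) {
    if (strategy == "C_residual") {
      if (qn == "gene") y <- quantile_normalize_to_normal(y)
      y <- stats::residuals(stats::lm(y ~ sex))
    }
    dv_one(y[sex == 0], y[sex == 1], strategy, alpha_normality, gate_scope)
  }))
  out <- data.frame(gene_id = rownames(vals), strategy = strategy,
                    branch = res[, "branch"],
                    statistic = as.numeric(res[, "statistic"]),
                    p = as.numeric(res[, "p"]),
                    direction = res[, "direction"],
                    stringsAsFactors = FALSE)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Differential mean expression between the sexes
#'
#' `method = "welch"` runs a per-gene Welch t-test on residual-scale values;
#' `method = "nb"` runs the negative-binomial exact test on counts (size
#' factors and dispersions estimated as in the accessibility module).
#'
#' @param expr an [expression_matrix]; kind must match the method.
#' @param sex optional 0/1 vector.
#' @param method `"welch"` or `"nb"`.
#' @return data.frame per gene: effect (mean difference F-M, or log2 fold
#'   F/M for nb), p, BH q, direction.
#' @export
test_de <- function(expr, sex = expr$samples$sex, method = c("welch", "nb")) {
  method <- match.arg(method)
  if (method == "welch") {
    if (expr$kind != "residuals") stop("welch DE expects residual-scale values")
    vals <- expr$values
    res <- t(apply(vals, 1, function(y) {
      if (stats::var(y) == 0) return(c(effect = 0, p = 1))
      tt <- welch_t(y[sex == 1], y[sex == 0])
      c(effect = tt$estimate, p = tt$p_value)
    }))
    out <- data.frame(gene_id = rownames(vals),
                      test = "welch",
                      effect = res[, "effect"], p = res[, "p"],
                      stringsAsFactors = FALSE)
  } else {
    if (expr$kind != "counts") stop("nb DE expects counts")
    nb <- nb_diff_test(expr$values, sex)
    out <- data.frame(gene_id = rownames(expr$values), test = "nb",
                      effect = nb$log2_fold, p = nb$p,
                      stringsAsFactors = FALSE)
  }
  out$q <- bh_fdr(out$p)
  out$direction <- ifelse(out$effect >= 0, "female", "male")
  rownames(out) <- NULL
  out
}

#' X-vs-autosome proportion comparison for a per-gene indicator
#'
#' One-sided Fisher's exact test of whether the proportion of flagged genes
#' is higher on chrX than on the autosomes.
#'
#' @param flags logical per gene (e.g. significant DV).
#' @param chrom chromosome per gene.
#' @param x_chrom names treated as X.
#' @return A `sexqtl_test` with `prop_x`/`prop_auto` attached as attributes.
#' @export
xa_proportion_test <- function(flags, chrom, x_chrom = c("chrX", "X")) {
  xi <- chrom %in% x_chrom
  if (!any(xi) || all(xi)) stop("need both X and autosomal genes")
  tab <- rbind(X = c(sum(flags & xi), sum(!flags & xi)),
               auto = c(sum(flags & !xi), sum(!flags & !xi)))
  tr <- fisher_exact(tab, sided = "greater", or_ci = TRUE)
  attr(tr, "prop_x") <- mean(flags[xi])
  attr(tr, "prop_auto") <- mean(flags[!xi])
  tr
}

#' Association between DV and DE gene sets
#'
#' Chi-squared test of the 2x2 overlap between differential-variance and
#' differential-expression flags, to check whether variance hits are simply
#' mean-shift hits.
#'
#' @param dv_flags,de_flags aligned logical vectors.
#' @return A `sexqtl_test`.
#' @export
dv_de_overlap_test <- function(dv_flags, de_flags) {
  if (!length(dv_flags) || length(dv_flags) != length(de_flags))
    stop("flag vectors must be nonempty and aligned")
  tab <- table(factor(dv_flags, c(FALSE, TRUE)), factor(de_flags, c(FALSE, TRUE)))
  chisq_2xk(as.matrix(tab))
}
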