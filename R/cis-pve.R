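# Per-sex cis heritability: proportion of expression variance explained
# (PVE) by common cis variants, via a single-component variance model
#   y = g + e,  g ~ N(0, sg2 * K),  e ~ N(0, se2 * I)
# with K the cis genetic relatedness matrix. REML by eigendecomposition of K
# and 1-D likelihood maximization over h2 = sg2/(sg2+se2); Haseman-Elston
# regression as the moment alternative.

#' Cis genetic relatedness matrix
#'
#' `K = Z Z' / m` with Z the column-standardized (mean 0, variance 1, using
#' the population 1/n denominator so `trace(K) = n` exactly) dosages of the
#' variants in the gene's cis window that pass the MAF filter.
#'
#' @param genotypes a [genotype_matrix].
#' @param variant_ids cis variants to use (rows of the dosage matrix).
#' @param sample_idx samples (stratum) to include; default all.
#' @param maf_min minimum sex-aware MAF (default 0.05).
#' @return list(K = n x n matrix, m = number of variants used), or NULL when
#'   no variant passes.
#' @export
cis_grm <- function(genotypes, variant_ids, sample_idx = NULL, maf_min = 0.05) {
  if (is.null(sample_idx)) sample_idx <- seq_len(ncol(genotypes$dosage))
  D <- genotypes$dosage[variant_ids, sample_idx, drop = FALSE]
  sex <- genotypes$samples$sex[sample_idx]
  xi <- is_x(genotypes)[match(variant_ids, rownames(genotypes$dosage))]
  keep <- vapply(seq_along(variant_ids), function(i) {
    d <- D[i, ]
    if (all(is.na(d))) return(FALSE)
    sex_aware_maf(d, sex, xi[i], genotypes$x_coding) >= maf_min
  }, logical(1))
  if (!any(keep)) return(NULL)
  Z <- t(D[keep, , drop = FALSE])
  Z[is.na(Z)] <- matrix(colMeans(Z, na.rm = TRUE), nrow(Z), ncol(Z),
                        byrow = TRUE)[is.na(Z)]
  n <- nrow(Z)
  mu <- colMeans(Z)
  sd_pop <- sqrt(colMeans(Z^2) - mu^2)
  ok <- sd_pop > 0
  if (!any(ok)) return(NULL)
  Z <- sweep(sweep(Z[, ok, drop = FALSE], 2, mu[ok]), 2, sd_pop[ok], "/")
  list(K = tcrossprod(Z) / ncol(Z), m = ncol(Z))
}

reml_h2_loglik <- function(h2, lambda, yt, xt) {
  w <- h2 * lambda + (1 - h2)
  xw <- sum(xt^2 / w)
  beta <- sum(xt * yt / w) / xw
  r <- yt - xt * beta
  n1 <- length(yt) - 1
  sp2 <- sum(r^2 / w) / n1
  -0.5 * (n1 * log(sp2) + sum(log(w)) + log(xw) + n1)
}

#' Estimate cis PVE for one gene in one sample stratum
#'
#' REML: profile restricted likelihood over `h2` in `[0, 1]` after rotating
#' by the GRM eigenvectors (intercept as the only fixed effect).
#' HE: Haseman-Elston regression of off-diagonal products of the
#' standardized phenotype on GRM entries, clipped to `[0, 1]`.
#'
#' @param y expression values for the stratum samples (residual scale).
#' @param grm output of [cis_grm].
#' @param estimator `"reml"` or `"he"`.
#' @return list: `pve`, `sg2`, `se2`, `n`, `m`, `estimator`.
#' @export
estimate_pve <- function(y, grm, estimator = c("reml", "he")) {
  estimator <- match.arg(estimator)
  K <- grm$K
  n <- length(y)
  stopifnot(nrow(K) == n)
  if (stats::var(y) == 0) stop("constant phenotype")
  if (estimator == "he") {
    ys <- (y - mean(y)) / stats::sd(y)
    P <- tcrossprod(ys)
    off <- upper.tri(K)
    h2 <- sum(K[off] * P[off]) / sum(K[off]^2)
    h2 <- min(1, max(0, h2))
    vp <- stats::var(y)
    return(list(pve = h2, sg2 = h2 * vp, se2 = (1 - h2) * vp,
                n = n, m = grm$m, estimator = "he"))
  }
  eg <- eigen(K, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  yt <- drop(crossprod(eg$vectors, y))
  xt <- drop(crossprod(eg$vectors, rep(1, n)))
  f <- function(h2) reml_h2_loglik(h2, lambda, yt, xt)
  opt <- stats::optimize(f, c(0, 1 - 1e-8), maximum = TRUE, tol = 1e-8)
  # optimize can miss boundary optima; check them explicitly
  cand <- c(opt$maximum, 0, 1 - 1e-8)
  ll <- vapply(cand, f, numeric(1))
  h2 <- cand[which.max(ll)]
  w <- h2 * lambda + (1 - h2)
  beta <- sum(xt * yt / w) / sum(xt^2 / w)
  sp2 <- sum((yt - xt * beta)^2 / w) / (n - 1)
  list(pve = h2, sg2 = h2 * sp2, se2 = (1 - h2) * sp2,
       n = n, m = grm$m, estimator = "reml")
}

#' Per-sex cis PVE across genes
#'
#' For each gene, builds the cis GRM from variants within the eQTL window and
#' estimates PVE separately in the male stratum and a size-matched female
#' stratum (so the comparison is not confounded by sample size).
#'
#' @param genotypes a [genotype_matrix].
#' @param expr an [expression_matrix] (residuals).
#' @param annotation a [gene_annotation].
#' @param window cis window in bp.
#' @param maf_min MAF filter for GRM variants.
#' @param estimator `"reml"` or `"he"`.
#' @param seed seed for the female size-matching subsample.
#' @return data.frame per gene x sex stratum with pve, sg2, se2, n, m.
#' @export
pve_by_sex <- function(genotypes, expr, annotation, window = 1e6,
                       maf_min = 0.05, estimator = "reml", seed = 1) {
  sex <- genotypes$samples$sex
  idx <- match_subsample(sex, seed)
  strata <- list(male = idx[sex[idx] == 0], female = idx[sex[idx] == 1])
  pairs <- cis_pairs(annotation, genotypes, window)
  out <- list()
  for (i in seq_len(nrow(annotation))) {
    gid <- annotation$gene_id[i]
    if (!gid %in% rownames(expr$values)) next
    vids <- pairs$variant_id[pairs$gene_id == gid]
    if (!length(vids)) next
    for (sx in names(strata)) {
      si <- strata[[sx]]
      grm <- cis_grm(genotypes, vids, si, maf_min)
      if (is.null(grm)) next
      est <- estimate_pve(expr$values[gid, si], grm, estimator)
      out[[length(out) + 1]] <- data.frame(
        gene_id = gid, stratum = sx, pve = est$pve, sg2 = est$sg2,
        se2 = est$se2, n = est$n, m = est$m, estimator = est$estimator,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Compare male and female PVE distributions
#'
#' Two-sided Wilcoxon rank-sum across genes plus the fold of mean PVE
#' (male / female).
#'
#' @param pve_m,pve_f per-gene PVE vectors for the two strata.
#' @return list: `fold` (mean male / mean female), `mean_m`, `mean_f`,
#'   `test` (a `sexqtl_test`).
#' @export
compare_pve <- function(pve_m, pve_f) {
  if (length(pve_m) < 10 || length(pve_f) < 10)
    stop("need at least 10 genes per stratum to compare PVE")
  list(fold = mean(pve_m) / mean(pve_f),
       mean_m = mean(pve_m), mean_f = mean(pve_f),
       test = wilcoxon_rank_sum(pve_m, pve_f))
}
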