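# cis-eQTL and genotype-by-sex interaction mapping.
#
# Additive model:     y = mu + b1*g + b2*sex + e
# Interaction model:  y = mu + b1*g + b2*sex + b3*(g*sex) + e,  e ~ N(0, s2)
# Sex is 0 = male, 1 = female, so b2, b3 > 0 mean larger in females.

ols_fit <- function(X, y, robust = FALSE) {
  fit <- stats::.lm.fit(X, y)
  p <- ncol(X); n <- length(y)
  df <- n - p
  rss <- sum(fit$residuals^2)
  s2 <- rss / df
  R <- qr.R(structure(list(qr = fit$qr, rank = fit$rank,
                           qraux = fit$qraux, pivot = fit$pivot),
                      class = "qr"))
  XtXinv <- chol2inv(R)
  piv <- fit$pivot
  if (robust) {
    # HC0 sandwich on the pivoted design
    Xp <- X[, piv, drop = FALSE]
    meat <- crossprod(Xp * fit$residuals)
    se <- sqrt(diag(XtXinv %*% meat %*% XtXinv))
  } else {
    se <- sqrt(diag(XtXinv) * s2)
  }
  # undo pivoting (coefficients and R are in pivoted column order)
  coef <- numeric(p); coef[piv] <- fit$coefficients
  se[piv] <- se
  tval <- coef / se
  list(coef = coef, se = se, t = tval,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       df = df, sigma2 = s2, n = n)
}

#' Residualize expression on known covariates and/or expression PCs
#'
#' Hidden-factor correction stage: regresses each gene on the supplied
#' covariate matrix and, optionally, on the leading principal components of
#' the expression matrix itself (a PCA-based stand-in for latent-factor
#' methods). Returns residual-scale expression ready for mapping.
#'
#' @param expr an [expression_matrix] (any kind; values used as given).
#' @param covariates optional sample x covariate numeric matrix.
#' @param n_pcs number of expression PCs to remove (default 0).
#' @return An [expression_matrix] of kind `"residuals"`.
#' @export
residualize_expression <- function(expr, covariates = NULL, n_pcs = 0) {
  Y <- expr$values
  X <- cbind(rep(1, ncol(Y)))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == ncol(Y))
    X <- cbind(X, covariates)
  }
  if (n_pcs > 0) {
    pcs <- stats::prcomp(t(Y), center = TRUE, scale. = FALSE)$x
    X <- cbind(X, pcs[, seq_len(min(n_pcs, ncol(pcs))), drop = FALSE])
  }
  Q <- qr.Q(qr(X))
  R <- Y - (Y %*% Q) %*% t(Q)
  expression_matrix(R, expr$samples, "residuals")
}

#' Enumerate cis gene-variant pairs
#'
#' A variant is cis to a gene when its position lies within `window` bp
#' upstream of the genomic TSS through `window` bp downstream of the genomic
#' TES (coordinates orientation-normalized, so the rule is symmetric in
#' strand), on the same chromosome.
#'
#' @param annotation a [gene_annotation].
#' @param genotypes a [genotype_matrix] (positions/chromosomes used).
#' @param window flanking distance in bp (default 1e6).
#' @return data.frame with columns `gene_id`, `variant_id`.
#' @export
cis_pairs <- function(annotation, genotypes, window = 1e6) {
  out <- lapply(seq_len(nrow(annotation)), function(i) {
    sel <- genotypes$chrom == annotation$chrom[i] &
      genotypes$pos >= annotation$tss[i] - window &
      genotypes$pos <= annotation$tes[i] + window
    if (!any(sel)) return(NULL)
    data.frame(gene_id = annotation$gene_id[i],
               variant_id = rownames(genotypes$dosage)[sel],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(gene_id = character(0),
                                      variant_id = character(0))
  out
}

#' Additive cis-eQTL fit for one gene-variant pair
#'
#' Ordinary least squares with classical standard errors; the joint stratum
#' includes sex as a covariate, single-sex strata drop it. Missing genotypes
#' are excluded pairwise (complete cases).
#'
#' @param y expression values (residual scale).
#' @param g genotype dosages (NA allowed).
#' @param sex 0/1 vector aligned with `y`.
#' @param stratum `"joint"`, `"male"` or `"female"`.
#' @param min_n minimum complete cases (default 30).
#' @param robust use HC0 heteroskedasticity-robust standard errors instead
#'   of the classical ones.
#' @return A one-row data.frame association record, or NULL when the fit is
#'   not possible (monomorphic genotype / too few samples).
#' @export
fit_additive <- function(y, g, sex, stratum = c("joint", "male", "female"),
                         min_n = 30, robust = FALSE) {
  stratum <- match.arg(stratum)
  keep <- !is.na(g) & !is.na(y)
  if (stratum == "male") keep <- keep & sex == 0
  if (stratum == "female") keep <- keep & sex == 1
  y <- y[keep]; g <- g[keep]; s <- sex[keep]
  if (length(y) < min_n) return(NULL)
  if (stats::var(g) == 0) return(NULL)
  X <- if (stratum == "joint") cbind(1, g, s) else cbind(1, g)
  f <- ols_fit(X, y, robust)
  data.frame(model = "additive", stratum = stratum,
             beta1 = f$coef[2], se1 = f$se[2], t1 = f$t[2], p = f$p[2],
             beta2 = if (stratum == "joint") f$coef[3] else NA_real_,
             se2 = if (stratum == "joint") f$se[3] else NA_real_,
             beta3 = NA_real_, se3 = NA_real_,
             mu = f$coef[1], sigma2 = f$sigma2, n = f$n,
             stringsAsFactors = FALSE)
}

#' Genotype-by-sex interaction fit for one gene-variant pair
#'
#' Fits `y = mu + b1 g + b2 sex + b3 g*sex + e`; the reported p-value is the
#' Wald t-test of the interaction coefficient `b3`. Variants failing the
#' collinearity rank filter are not fitted (NULL returned).
#'
#' @inheritParams fit_additive
#' @return A one-row data.frame record (p is the interaction p), or NULL.
#' @export
fit_interaction <- function(y, g, sex, min_n = 30, robust = FALSE) {
  keep <- !is.na(g) & !is.na(y)
  y <- y[keep]; g <- g[keep]; s <- sex[keep]
  if (length(y) < min_n) return(NULL)
  if (!collinearity_filter(g, s)$keep) return(NULL)
  X <- cbind(1, g, s, g * s)
  if (qr(X)$rank < 4) return(NULL)
  f <- ols_fit(X, y, robust)
  data.frame(model = "interaction", stratum = "joint",
             beta1 = f$coef[2], se1 = f$se[2], t1 = f$t[2],
             p = f$p[4],
             beta2 = f$coef[3], se2 = f$se[3],
             beta3 = f$coef[4], se3 = f$se[4],
             mu = f$coef[1], sigma2 = f$sigma2, n = f$n,
             stringsAsFactors = FALSE)
}

#' Genotype/sex collinearity filter
#'
#' A variant enters the interaction scan only when the column set
#' `{1, genotype, sex}` has numerical rank 3 (singular values above
#' `tol * largest`). Rank < 3 means genotype is (nearly) a linear function of
#' sex and the interaction is not identifiable.
#'
#' @param g genotype dosages (complete cases).
#' @param sex 0/1 vector.
#' @param tol relative singular-value tolerance (default 1e-8).
#' @return list(keep = logical, rank = integer, reason = character).
#' @export
collinearity_filter <- function(g, sex, tol = 1e-8) {
  X <- cbind(1, g, sex)
  d <- svd(X, nu = 0, nv = 0)$d
  r <- sum(d > tol * d[1])
  list(keep = r >= 3,
       rank = r,
       reason = if (r >= 3) "" else "genotype collinear with sex")
}

#' Gene-level hierarchical FDR summary
#'
#' Per gene: Bonferroni-adjust the best nominal p by the number of variants
#' actually tested for that gene, retain the best association, then
#' Benjamini-Hochberg across genes' best associations. Ties on p are broken
#' lexicographically on variant_id, making the summary deterministic.
#'
#' @param records data.frame with columns `gene_id`, `variant_id`, `p`.
#' @return data.frame: `gene_id`, `n_tests`, `best_variant`, `best_p`,
#'   `bonf_p`, `q`.
#' @export
gene_level_fdr <- function(records) {
  stopifnot(all(c("gene_id", "variant_id", "p") %in% names(records)))
  if (!nrow(records))
    return(data.frame(gene_id = character(0), n_tests = integer(0),
                      best_variant = character(0), best_p = numeric(0),
                      bonf_p = numeric(0), q = numeric(0)))
  ord <- order(records$gene_id, records$p, records$variant_id)
  records <- records[ord, , drop = FALSE]
  first <- !duplicated(records$gene_id)
  n_tests <- as.integer(table(records$gene_id)[records$gene_id[first]])
  out <- data.frame(gene_id = records$gene_id[first],
                    n_tests = n_tests,
                    best_variant = records$variant_id[first],
                    best_p = records$p[first],
                    stringsAsFactors = FALSE)
  out$bonf_p <- bonferroni(out$best_p, out$n_tests)
  out$q <- bh_fdr(out$bonf_p)
  rownames(out) <- NULL
  out
}

#' Map cis-eQTLs (additive or interaction model) across all genes
#'
#' Applies the MAF filter (sex-aware on chrX; the interaction model requires
#' the MAF bound within each sex separately), the collinearity filter for the
#' interaction model, fits each retained pair, and summarizes genes with the
#' hierarchical Bonferroni-then-BH procedure.
#'
#' @param genotypes a [genotype_matrix].
#' @param expr an [expression_matrix] (kind "residuals").
#' @param annotation a [gene_annotation].
#' @param model `"additive"` or `"interaction"`.
#' @param stratum for the additive model: `"joint"`, `"male"`, `"female"`.
#' @param window cis window in bp.
#' @param maf_range keep variants with MAF in `[maf_range[1], maf_range[2]]`
#'   (default common variants, `c(0.05, 0.5)`).
#' @param restrict_variants optional named list `gene_id -> variant_ids`
#'   restricting the interaction scan to prior cis-eQTL variants.
#' @return list with `records` (all fitted pairs), `summary` (gene-level
#'   FDR table) and `filter_counts`.
#' @export
map_cis_eqtl <- function(genotypes, expr, annotation,
                         model = c("additive", "interaction"),
                         stratum = "joint", window = 1e6,
                         maf_range = c(0.05, 0.5),
                         restrict_variants = NULL) {
  model <- match.arg(model)
  stopifnot(identical(expr$samples$sample_id, genotypes$samples$sample_id))
  sex <- genotypes$samples$sex
  pairs <- cis_pairs(annotation, genotypes, window)
  pairs <- pairs[pairs$gene_id %in% rownames(expr$values), , drop = FALSE]
  counts <- c(pairs = nrow(pairs), maf_fail = 0L, collinear = 0L,
              not_fitted = 0L, fitted = 0L)
  xi <- stats::setNames(is_x(genotypes), rownames(genotypes$dosage))
  recs <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    gid <- pairs$gene_id[i]; vid <- pairs$variant_id[i]
    if (!is.null(restrict_variants) &&
        !(vid %in% restrict_variants[[gid]])) next
    g <- genotypes$dosage[vid, ]
    ok <- !is.na(g)
    maf_ok <- if (model == "interaction") {
      mm <- try(sex_aware_maf(g[sex == 0], sex[sex == 0], xi[vid],
                              genotypes$x_coding), silent = TRUE)
      mf <- try(sex_aware_maf(g[sex == 1], sex[sex == 1], xi[vid],
                              genotypes$x_coding), silent = TRUE)
      !inherits(mm, "try-error") && !inherits(mf, "try-error") &&
        mm >= maf_range[1] && mm <= maf_range[2] &&
        mf >= maf_range[1] && mf <= maf_range[2]
    } else {
      maf <- sex_aware_maf(g, sex, xi[vid], genotypes$x_coding)
      maf >= maf_range[1] && maf <= maf_range[2]
    }
    if (!maf_ok) { counts["maf_fail"] <- counts["maf_fail"] + 1L; next }
    y <- expr$values[gid, ]
    rec <- if (model == "additive") {
      fit_additive(y, g, sex, stratum)
    } else {
      if (!collinearity_filter(g[ok], sex[ok])$keep) {
        counts["collinear"] <- counts["collinear"] + 1L
        NULL
      } else fit_interaction(y, g, sex)
    }
    if (is.null(rec)) { counts["not_fitted"] <- counts["not_fitted"] + 1L; next }
    rec$gene_id <- gid; rec$variant_id <- vid
    recs[[i]] <- rec
    counts["fitted"] <- counts["fitted"] + 1L
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(records))
    records <- data.frame(gene_id = character(0), variant_id = character(0),
                          p = numeric(0))
  list(records = records, summary = gene_level_fdr(records),
       filter_counts = counts)
}

#' X-vs-autosome eQTL discovery-rate comparison
#'
#' Per FDR threshold, a 2x2 chi-squared test of the proportion of genes with
#' an eQTL (gene-level q below threshold) on chrX versus autosomes, with a
#' Bonferroni adjustment over the threshold grid.
#'
#' @param summary a [gene_level_fdr] table.
#' @param chrom chromosome label per summary row.
#' @param fdr_grid FDR thresholds to scan.
#' @param x_chrom chromosome names counted as X.
#' @return data.frame per threshold: discovery proportions, chi-squared p and
#'   Bonferroni-adjusted p (NA when a threshold has no discoveries).
#' @export
xa_eqtl_depletion <- function(summary, chrom,
                              fdr_grid = c(0.01, 0.05, 0.1),
                              x_chrom = c("chrX", "X")) {
  xi <- chrom %in% x_chrom
  if (!any(xi) || all(xi)) stop("need both X and autosomal genes")
  res <- lapply(fdr_grid, function(thr) {
    sig <- summary$q < thr
    if (!any(sig))
      return(data.frame(fdr = thr, prop_x = 0, prop_auto = 0,
                        p = NA_real_))
    tab <- rbind(X = c(sum(sig & xi), sum(!sig & xi)),
                 auto = c(sum(sig & !xi), sum(!sig & !xi)))
    data.frame(fdr = thr, prop_x = mean(sig[xi]), prop_auto = mean(sig[!xi]),
               p = chisq_2xk(tab)$p_value)
  })
  out <- do.call(rbind, res)
  out$p_bonf <- bonferroni(out$p, sum(!is.na(out$p)))
  out
}

#' Compare eQTL effect-size magnitudes between two record sets
#'
#' Two-sided Wilcoxon on `|beta1|`; optionally per quantile bin of a supplied
#' per-record score (e.g. a selective-constraint measure).
#'
#' @param records_a,records_b association record data.frames (significant
#'   associations; `beta1` used).
#' @param score_a,score_b optional numeric score per record for binning.
#' @param n_bins number of quantile bins when scores are given.
#' @return data.frame with fold of mean `|beta1|` (a/b) and Wilcoxon p;
#'   one row per bin (bin NA = overall). Bins with < 5 records on either
#'   side report NA.
#' @export
effect_size_compare <- function(records_a, records_b,
                                score_a = NULL, score_b = NULL, n_bins = 5) {
  cmp <- function(a, b) {
    if (length(a) < 5 || length(b) < 5)
      return(data.frame(fold = NA_real_, p = NA_real_,
                        n_a = length(a), n_b = length(b)))
    data.frame(fold = mean(a) / mean(b),
               p = wilcoxon_rank_sum(a, b)$p_value,
               n_a = length(a), n_b = length(b))
  }
  a <- abs(records_a$beta1); b <- abs(records_b$beta1)
  out <- cbind(bin = NA_integer_, cmp(a, b))
  if (!is.null(score_a)) {
    edges <- stats::quantile(c(score_a, score_b),
                             probs = seq(0, 1, length.out = n_bins + 1))
    edges[1] <- -Inf; edges[n_bins + 1] <- Inf
    ba <- cut(score_a, edges, labels = FALSE)
    bb <- cut(score_b, edges, labels = FALSE)
    for (k in seq_len(n_bins))
      out <- rbind(out, cbind(bin = k, cmp(a[ba == k], b[bb == k])))
  }
  rownames(out) <- NULL
  out
}

#' Top-K QQ enrichment of X-linked association p-values
#'
#' One-sided Wilcoxon comparing the `top_k` smallest p-values (as -log10)
#' from chrX associations against the `top_k` smallest autosomal ones;
#' rejects when the X tail is more enriched.
#'
#' @param p_x,p_auto nominal p-value vectors.
#' @param top_k number of top associations per group (>= 2).
#' @return A `sexqtl_test`.
#' @export
qq_enrichment <- function(p_x, p_auto, top_k = 50) {
  if (top_k < 2) stop("top_k must be >= 2")
  if (length(p_x) < top_k || length(p_auto) < top_k)
    stop("top_k exceeds available associations")
  lx <- -log10(sort(p_x)[seq_len(top_k)])
  la <- -log10(sort(p_auto)[seq_len(top_k)])
  wilcoxon_rank_sum(lx, la, sided = "greater")
}
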