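# Cumulative sex bias of eQTL effect sizes at trait-associated variants:
# LD-prune each trait's variants, measure each variant's absolute cis effect
# in males and a size-matched female subsample, classify by the 1.2-fold
# rule, and run a two-sided exact binomial test per trait.

#' Greedy LD pruning of a trait's catalog variants
#'
#' Variants are sorted by GWAS p-value ascending (ties broken
#' lexicographically on variant_id); each is kept iff its r-squared with
#' every already-kept variant is below `r2_max`. Missing r-squared entries
#' are treated as 0 (independent) and counted.
#'
#' @param variant_id,gwas_p vectors for one trait.
#' @param r2 symmetric matrix of pairwise r-squared with variant_id dimnames.
#' @param r2_max pruning threshold (default 0.5).
#' @return list: `kept` variant ids (in selection order), `n_missing_r2`.
#' @export
ld_prune <- function(variant_id, gwas_p, r2, r2_max = 0.5) {
  ord <- order(gwas_p, variant_id)
  ids <- variant_id[ord]
  kept <- character(0)
  n_missing <- 0L
  for (v in ids) {
    ok <- TRUE
    for (w in kept) {
      val <- if (v %in% rownames(r2) && w %in% colnames(r2)) r2[v, w] else NA
      if (is.na(val)) { n_missing <- n_missing + 1L; val <- 0 }
      if (val >= r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, v)
  }
  if (n_missing > 0) warning(n_missing, " missing r2 entries treated as 0")
  list(kept = kept, n_missing_r2 = n_missing)
}

#' Pairwise genotype r-squared
#'
#' Squared Pearson correlation of dosages (complete pairs).
#'
#' @param genotypes a [genotype_matrix].
#' @param variant_ids variants to correlate.
#' @return Symmetric matrix with variant_id dimnames.
#' @export
genotype_r2 <- function(genotypes, variant_ids) {
  D <- t(genotypes$dosage[variant_ids, , drop = FALSE])
  r <- suppressWarnings(stats::cor(D, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  r^2
}

#' Per-sex absolute eQTL effect of one variant
#'
#' Among the genes whose cis window (TSS - window to TES + window) contains
#' the variant, picks the gene with the best joint additive eQTL p-value
#' (requiring `p < p_gate`), then refits the additive model separately in
#' the male stratum and in a seeded female subsample of equal size.
#'
#' @param variant_id one variant.
#' @param genotypes a [genotype_matrix].
#' @param expr an [expression_matrix].
#' @param annotation a [gene_annotation].
#' @param window cis window in bp.
#' @param p_gate nominal joint eQTL significance gate (default 1e-3).
#' @param seed seed for the female subsample.
#' @return list(`gene_id`, `beta_m`, `beta_f`, `joint_p`) or NULL when no
#'   cis gene passes the gate.
#' @export
per_sex_effects <- function(variant_id, genotypes, expr, annotation,
                            window = 1e6, p_gate = 1e-3, seed = 1) {
  vi <- match(variant_id, rownames(genotypes$dosage))
  if (is.na(vi)) return(NULL)
  g <- genotypes$dosage[vi, ]
  sex <- genotypes$samples$sex
  cis <- annotation$chrom == genotypes$chrom[vi] &
    genotypes$pos[vi] >= annotation$tss - window &
    genotypes$pos[vi] <= annotation$tes + window
  gids <- intersect(annotation$gene_id[cis], rownames(expr$values))
  if (!length(gids)) return(NULL)
  joint <- lapply(gids, function(gid) {
    r <- fit_additive(expr$values[gid, ], g, sex, "joint")
    if (is.null(r)) NULL else data.frame(gene_id = gid, p = r$p)
  })
  joint <- do.call(rbind, joint[!vapply(joint, is.null, logical(1))])
  if (is.null(joint) || min(joint$p) >= p_gate) return(NULL)
  best <- joint$gene_id[order(joint$p, joint$gene_id)][1]
  idx <- match_subsample(sex, seed)
  y <- expr$values[best, idx]; gg <- g[idx]; ss <- sex[idx]
  fm <- fit_additive(y, gg, ss, "male", min_n = 10)
  ff <- fit_additive(y, gg, ss, "female", min_n = 10)
  if (is.null(fm) || is.null(ff)) return(NULL)
  list(gene_id = best, beta_m = abs(fm$beta1), beta_f = abs(ff$beta1),
       joint_p = min(joint$p))
}

#' Classify a variant's sex bias by the fold rule
#'
#' Female-biased iff `|beta_f| >= fold * |beta_m|`, male-biased iff
#' `|beta_m| >= fold * |beta_f|` (the boundary counts as biased), otherwise
#' unclassified.
#'
#' @param beta_m,beta_f absolute per-sex effects.
#' @param fold bias threshold (default 1.2).
#' @return `"female"`, `"male"` or `"none"`.
#' @export
classify_bias <- function(beta_m, beta_f, fold = 1.2) {
  stopifnot(is.finite(beta_m), is.finite(beta_f))
  if (beta_m == 0 && beta_f == 0) return("none")
  if (beta_f >= fold * beta_m) return("female")
  if (beta_m >= fold * beta_f) return("male")
  "none"
}

#' Per-trait sex-bias binomial test
#'
#' For each trait with at least `min_variants` classified (sex-biased)
#' variants, a two-sided exact binomial test of female-biased among biased
#' variants against 0.5, Bonferroni-adjusted across tested traits.
#'
#' @param classifications data.frame with columns `trait`, `bias`
#'   (female/male/none).
#' @param min_variants minimum biased variants per trait (default 20).
#' @return data.frame per tested trait: counts, proportion female-biased,
#'   binomial p, Bonferroni p, direction.
#' @export
trait_bias_test <- function(classifications, min_variants = 20) {
  out <- lapply(split(classifications, classifications$trait), function(d) {
    nf <- sum(d$bias == "female"); nm <- sum(d$bias == "male")
    data.frame(trait = d$trait[1], n_tested = nrow(d), n_female = nf,
               n_male = nm, n_none = sum(d$bias == "none"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$n_female + out$n_male >= min_variants, , drop = FALSE]
  if (!nrow(out)) {
    out$prop_female <- out$p <- out$p_bonf <- numeric(0)
    out$direction <- character(0)
    return(out)
  }
  out$prop_female <- out$n_female / (out$n_female + out$n_male)
  out$p <- vapply(seq_len(nrow(out)), function(i) {
    nb <- out$n_female[i] + out$n_male[i]
    if (nb == 0) return(1)
    binomial_exact(out$n_female[i], nb)$p_value
  }, numeric(1))
  out$p_bonf <- bonferroni(out$p, nrow(out))
  out$direction <- ifelse(out$prop_female >= 0.5, "female", "male")
  rownames(out) <- NULL
  out
}

#' End-to-end GWAS sex-bias analysis
#'
#' LD-prunes each trait, gates and measures per-sex effects, classifies by
#' the fold rule and tests each trait. Optionally appends a random-variant
#' control trait ("RND") drawn from all catalog variants.
#'
#' @param catalog a [gwas_catalog].
#' @param genotypes,expr,annotation cohort data.
#' @param r2 pairwise r-squared matrix (default computed from genotypes).
#' @param window,p_gate,fold,min_variants,r2_max analysis parameters.
#' @param seed seed for the female subsample (and the RND draw).
#' @param add_random append a random control trait of this many variants
#'   (0 = none).
#' @return list: `traits` ([trait_bias_test] table), `variants` (per-variant
#'   classification table).
#' @export
gwas_sexbias <- function(catalog, genotypes, expr, annotation, r2 = NULL,
                         window = 1e6, p_gate = 1e-3, fold = 1.2,
                         min_variants = 20, r2_max = 0.5, seed = 1,
                         add_random = 0) {
  if (!nrow(catalog)) return(list(traits = NULL, variants = NULL))
  if (add_random > 0) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(seed + 104729L)
    pool <- unique(catalog$variant_id)
    rnd <- sample(pool, min(add_random, length(pool)))
    i <- match(rnd, catalog$variant_id)
    catalog <- rbind(catalog,
                     gwas_catalog("RND", rnd, catalog$gwas_p[i],
                                  catalog$chrom[i], catalog$pos[i]))
  }
  if (is.null(r2))
    r2 <- genotype_r2(genotypes,
                      intersect(unique(catalog$variant_id),
                                rownames(genotypes$dosage)))
  rows <- list()
  for (tr in unique(catalog$trait)) {
    d <- catalog[catalog$trait == tr, , drop = FALSE]
    kept <- ld_prune(d$variant_id, d$gwas_p, r2, r2_max)$kept
    for (v in kept) {
      eff <- per_sex_effects(v, genotypes, expr, annotation, window,
                             p_gate, seed)
      if (is.null(eff)) next
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, variant_id = v, gene_id = eff$gene_id,
        beta_m = eff$beta_m, beta_f = eff$beta_f, joint_p = eff$joint_p,
        bias = classify_bias(eff$beta_m, eff$beta_f, fold),
        stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, rows)
  if (is.null(variants))
    return(list(traits = NULL, variants = NULL))
  list(traits = trait_bias_test(variants, min_variants), variants = variants)
}
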