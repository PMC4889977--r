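# Synthetic cohort generator with known ground truth.
#
# Emulates a DGN-like whole-blood cohort: 922 individuals (648 female, 274
# male), Hardy-Weinberg genotypes without LD inside cis windows (optional
# copy-with-mutation LD proxies for catalog variants), expression built from
# the generative mirror of the mapping model
#   y = mu + b1*g + b2*s + b3*g*s + e,  e ~ N(0, sigma_sex^2),
# male X hemizygosity through the dosage coding, X-inactivation-escape
# female mean shifts in expression and upstream peak signal, allelic read
# counts from the ASE GLMM, NB peak counts with per-sample library factors,
# and a GWAS catalog tagging simulated eQTLs with sex-biased effects.

#' Simulation configuration
#'
#' Defaults mirror the emulated cohort (648 F / 274 M) and desk-scale gene
#' counts; all knobs are exposed.
#'
#' @param n_male,n_female cohort sizes.
#' @param n_genes_auto,n_genes_x genes per chromosome class.
#' @param variants_per_gene cis variants simulated per gene.
#' @param maf_range allele-frequency range (uniform draw).
#' @param beta1,beta2,beta3 effect mixtures: `list(prop, sd)` = proportion of
#'   genes with a nonzero effect and its SD.
#' @param dv_prop,dv_ratio fraction of genes with sex-specific residual SD
#'   and the sigma_f/sigma_m ratio applied (half of DV genes get the inverse).
#' @param escape_fraction fraction of X genes escaping X-inactivation.
#' @param escape_shift female mean-expression increase for escape genes.
#' @param nb_dispersion NB dispersion for count matrices.
#' @param count_base,count_scale log-mean intercept and residual-to-log-mean
#'   scale for the count version of expression.
#' @param ase ASE settings: `list(n_genes, n_het_per_sex, lambda, gamma_sd,
#'   delta_prop, delta, tau)`.
#' @param peaks ATAC settings: `list(n_background, n_per_sex, lfc,
#'   sex_specific_prop, link_prop, base_log_mean, lib_sd)`.
#' @param gwas catalog settings: `list(n_biased, n_null_traits, n_null,
#'   beta1, beta3, proxy_prop, proxy_r2)`.
#' @param x_coding male chrX dosage coding.
#' @param seed integer seed (reproducible).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_male = 274, n_female = 648,
                       n_genes_auto = 60, n_genes_x = 30,
                       variants_per_gene = 5,
                       maf_range = c(0.05, 0.5),
                       beta1 = list(prop = 0.3, sd = 0.3),
                       beta2 = list(prop = 0.2, sd = 0.5),
                       beta3 = list(prop = 0.1, sd = 0.3),
                       dv_prop = 0.1, dv_ratio = 2,
                       escape_fraction = 0.2, escape_shift = 0.5,
                       nb_dispersion = 0.2,
                       count_base = log(200), count_scale = 0.4,
                       ase = list(n_genes = 20, n_het_per_sex = 30,
                                  lambda = 50, gamma_sd = 0.3,
                                  delta_prop = 0.2, delta = 0.8, tau = 0.2),
                       peaks = list(n_background = 200, n_per_sex = 10,
                                    lfc = 1.5, sex_specific_prop = 0.05,
                                    link_prop = 0.3, base_log_mean = log(100),
                                    lib_sd = 0.2),
                       gwas = list(n_biased = 0, n_null_traits = 0,
                                   n_null = 20, beta1 = 0.25, beta3 = 0.2,
                                   proxy_prop = 0.5, proxy_r2 = c(0.6, 0.95)),
                       x_coding = "full_dosage", seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_male > 0, cfg$n_female > 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            beta1$prop >= 0, beta1$prop <= 1, beta1$sd > 0,
            dv_prop >= 0, dv_prop <= 1, dv_ratio > 0,
            escape_fraction >= 0, escape_fraction <= 1,
            nb_dispersion >= 0, ase$lambda > 0)
  n_gwas_genes <- gwas$n_biased + gwas$n_null_traits * gwas$n_null
  if (n_gwas_genes > n_genes_auto)
    stop("not enough autosomal genes for the requested GWAS traits")
  structure(cfg, class = "sim_config")
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  expr
}

# Gene/variant plan plus per-gene truth (effects, variances, escape, trait).
plan_cohort <- function(cfg) {
  with_seed(cfg$seed, {
    n_genes <- cfg$n_genes_auto + cfg$n_genes_x
    chrom <- rep(c("chr1", "chrX"), c(cfg$n_genes_auto, cfg$n_genes_x))
    idx_in_chr <- c(seq_len(cfg$n_genes_auto), seq_len(cfg$n_genes_x))
    tss <- 2e6 + (idx_in_chr - 1) * 5e6   # disjoint 1 Mb cis windows
    tes <- tss + 1e4
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    gene_id <- sprintf("gene_%s_%03d", ifelse(chrom == "chrX", "X", "A"),
                       seq_len(n_genes))
    ann <- gene_annotation(gene_id, chrom, tss, tes, strand)

    draw_mix <- function(mix) ifelse(stats::runif(n_genes) < mix$prop,
                                     stats::rnorm(n_genes, 0, mix$sd), 0)
    beta1 <- draw_mix(cfg$beta1)
    beta2 <- draw_mix(cfg$beta2)
    beta3 <- draw_mix(cfg$beta3)
    dv <- stats::runif(n_genes) < cfg$dv_prop
    ratio <- ifelse(dv, ifelse(stats::runif(n_genes) < 0.5,
                               cfg$dv_ratio, 1 / cfg$dv_ratio), 1)
    sigma_m <- rep(1, n_genes)
    sigma_f <- sigma_m * ratio
    escape <- chrom == "chrX" & stats::runif(n_genes) < cfg$escape_fraction
    beta2[escape] <- beta2[escape] + cfg$escape_shift

    trait <- rep(NA_character_, n_genes)
    n_gwas <- cfg$gwas$n_biased + cfg$gwas$n_null_traits * cfg$gwas$n_null
    if (n_gwas > 0) {
      gw <- sample(which(chrom == "chr1"), n_gwas)
      labels <- c(rep("BIASED", cfg$gwas$n_biased),
                  rep(sprintf("NULL%d", seq_len(cfg$gwas$n_null_traits)),
                      each = cfg$gwas$n_null))
      trait[gw] <- labels
      beta1[gw] <- cfg$gwas$beta1 * sample(c(-1, 1), n_gwas, replace = TRUE)
      beta3[gw] <- ifelse(labels == "BIASED",
                          cfg$gwas$beta3 * sign(beta1[gw]), 0)
    }

    list(annotation = ann,
         genes = data.frame(gene_id = gene_id, chrom = chrom,
                            causal_variant = paste0(gene_id, "_v1"),
                            beta1 = beta1, beta2 = beta2, beta3 = beta3,
                            sigma_m = sigma_m, sigma_f = sigma_f,
                            escape = escape, trait = trait,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate cohort genotypes
#'
#' Per variant, allele frequency ~ Uniform(maf_range); autosomal dosage ~
#' Binomial(2, f); chrX: females Binomial(2, f), males Bernoulli(f) scaled by
#' the coding. Variants are laid out in each gene's cis window
#' (`variants_per_gene` per gene, the first being the causal one).
#'
#' @param cfg a [sim_config].
#' @param plan internal gene plan (computed if NULL).
#' @param seed seed (default `cfg$seed + 1`).
#' @return list: `genotypes` ([genotype_matrix]), `samples`, `proxy_map`
#'   (data.frame of LD proxies added for catalog variants).
#' @export
simulate_genotypes <- function(cfg, plan = NULL, seed = cfg$seed + 1) {
  if (is.null(plan)) plan <- plan_cohort(cfg)
  ann <- plan$annotation
  samples <- sample_info(
    c(sprintf("M%04d", seq_len(cfg$n_male)),
      sprintf("F%04d", seq_len(cfg$n_female))),
    rep(c(0L, 1L), c(cfg$n_male, cfg$n_female)))
  n <- nrow(samples)
  male <- samples$sex == 0L
  with_seed(seed, {
    rows <- list(); chroms <- character(0); poss <- integer(0)
    draw_variant <- function(f, on_x) {
      if (!on_x) return(stats::rbinom(n, 2, f))
      d <- integer(n)
      a <- stats::rbinom(sum(male), 1, f)
      d[male] <- if (cfg$x_coding == "full_dosage") 2L * a else a
      d[!male] <- stats::rbinom(sum(!male), 2, f)
      d
    }
    proxy <- list()
    for (i in seq_len(nrow(ann))) {
      on_x <- ann$chrom[i] == "chrX"
      offs <- round(seq(-9e5, 9e5, length.out = cfg$variants_per_gene))
      for (v in seq_len(cfg$variants_per_gene)) {
        f <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
        vid <- sprintf("%s_v%d", ann$gene_id[i], v)
        d <- draw_variant(f, on_x)
        rows[[vid]] <- d
        chroms <- c(chroms, ann$chrom[i])
        poss <- c(poss, ann$tss[i] + offs[v])
        is_trait <- v == 1 && !is.na(plan$genes$trait[i])
        if (is_trait && stats::runif(1) < cfg$gwas$proxy_prop) {
          r2 <- stats::runif(1, cfg$gwas$proxy_r2[1], cfg$gwas$proxy_r2[2])
          rho <- sqrt(r2)
          # copy-with-mutation at the allele level: corr(alleles) = rho
          mutate <- function(alle, n_all) {
            keep <- stats::runif(n_all) < rho
            ifelse(keep, alle, stats::rbinom(n_all, 1, f))
          }
          if (on_x) {
            dp <- integer(n)
            a <- if (cfg$x_coding == "full_dosage") d[male] / 2 else d[male]
            ap <- mutate(a, sum(male))
            dp[male] <- if (cfg$x_coding == "full_dosage") 2L * ap else ap
            a1 <- stats::rbinom(sum(!male), 1, 0.5)  # split female dosage
            h1 <- pmin(d[!male], 1) * (d[!male] == 2 | a1 == 1)
            h2 <- d[!male] - h1
            dp[!male] <- mutate(h1, sum(!male)) + mutate(h2, sum(!male))
          } else {
            a1 <- stats::rbinom(n, 1, 0.5)
            h1 <- pmin(d, 1) * (d == 2 | a1 == 1)
            h2 <- d - h1
            dp <- mutate(h1, n) + mutate(h2, n)
          }
          pid <- paste0(vid, "_proxy")
          rows[[pid]] <- as.integer(dp)
          chroms <- c(chroms, ann$chrom[i])
          poss <- c(poss, ann$tss[i] + offs[v] + 500L)
          proxy[[length(proxy) + 1]] <-
            data.frame(variant_id = vid, proxy_id = pid, target_r2 = r2,
                       stringsAsFactors = FALSE)
        }
      }
    }
    dosage <- do.call(rbind, rows)
    g <- genotype_matrix(dosage, chroms, poss, samples, cfg$x_coding)
    proxy_map <- if (length(proxy)) do.call(rbind, proxy) else
      data.frame(variant_id = character(0), proxy_id = character(0),
                 target_r2 = numeric(0))
    list(genotypes = g, samples = samples, proxy_map = proxy_map)
  })
}

#' Simulate expression from genotypes and truth effects
#'
#' Residual scale: `y = b1 g + b2 s + b3 g s + e`, `e ~ N(0, sigma_sex^2)`,
#' with `g` the coded dosage of the gene's causal variant. The count version
#' draws `NB(mean = exp(count_base + count_scale * y), size = 1/dispersion)`.
#'
#' @param genotypes a [genotype_matrix].
#' @param truth_genes per-gene truth table (see [plan_cohort] fields).
#' @param cfg a [sim_config].
#' @param seed seed (default `cfg$seed + 2`).
#' @return list: `residuals` and `counts` ([expression_matrix] objects).
#' @export
simulate_expression <- function(genotypes, truth_genes, cfg,
                                seed = cfg$seed + 2) {
  samples <- genotypes$samples
  s <- samples$sex
  n <- length(s)
  with_seed(seed, {
    Y <- matrix(NA_real_, nrow(truth_genes), n,
                dimnames = list(truth_genes$gene_id, samples$sample_id))
    for (i in seq_len(nrow(truth_genes))) {
      g <- genotypes$dosage[truth_genes$causal_variant[i], ]
      sig <- ifelse(s == 1, truth_genes$sigma_f[i], truth_genes$sigma_m[i])
      Y[i, ] <- truth_genes$beta1[i] * g + truth_genes$beta2[i] * s +
        truth_genes$beta3[i] * g * s + stats::rnorm(n, 0, sig)
    }
    mu <- exp(cfg$count_base + cfg$count_scale * Y)
    K <- matrix(stats::rnbinom(length(mu), mu = mu,
                               size = 1 / max(cfg$nb_dispersion, 1e-8)),
                nrow(mu), dimnames = dimnames(mu))
    list(residuals = expression_matrix(Y, samples, "residuals"),
         counts = expression_matrix(K, samples, "counts"))
  })
}

#' Simulate allele-specific expression counts
#'
#' For each ASE gene, `n_het_per_sex` heterozygous individuals per sex with
#' phased contrast `h = +/-1`; total reads ~ Poisson(lambda) + 1 (floor);
#' alt reads ~ Binomial(total, logistic(alpha + gamma h + delta h s + u_i)),
#' `u_i ~ N(0, tau^2)`.
#'
#' @param truth_genes per-gene truth table (first `ase$n_genes` genes used).
#' @param cfg a [sim_config].
#' @param seed seed (default `cfg$seed + 3`).
#' @return list: `ase` ([ase_table]), `truth` (per-gene alpha/gamma/delta/tau).
#' @export
simulate_ase <- function(truth_genes, cfg, seed = cfg$seed + 3) {
  ac <- cfg$ase
  if (ac$lambda <= 0) stop("ASE read depth lambda must be > 0")
  gene_ids <- utils::head(truth_genes$gene_id, ac$n_genes)
  with_seed(seed, {
    truth <- data.frame(gene_id = gene_ids,
                        alpha = 0,
                        gamma = stats::rnorm(length(gene_ids), 0, ac$gamma_sd),
                        delta = ifelse(stats::runif(length(gene_ids)) < ac$delta_prop,
                                       ac$delta, 0),
                        tau = ac$tau, stringsAsFactors = FALSE)
    rows <- list()
    for (i in seq_along(gene_ids)) {
      n_ind <- 2 * ac$n_het_per_sex
      sex <- rep(c(0L, 1L), each = ac$n_het_per_sex)
      h <- sample(c(-1L, 1L), n_ind, replace = TRUE)
      u <- stats::rnorm(n_ind, 0, ac$tau)
      tot <- stats::rpois(n_ind, ac$lambda) + 1L
      p <- stats::plogis(truth$alpha[i] + truth$gamma[i] * h +
                           truth$delta[i] * h * sex + u)
      alt <- stats::rbinom(n_ind, tot, p)
      rows[[i]] <- data.frame(
        individual = sprintf("ind%03d", seq_len(n_ind)),
        gene_id = gene_ids[i], site = paste0(gene_ids[i], "_s1"),
        ref_count = tot - alt, alt_count = alt, h = h, sex = sex,
        stringsAsFactors = FALSE)
    }
    list(ase = ase_table(do.call(rbind, rows)), truth = truth)
  })
}

#' Simulate an ATAC peak count matrix with truth
#'
#' One peak in the strand-oriented 40-kb upstream window of every gene plus
#' background peaks. X-escape genes get a female-open upstream peak; a
#' `link_prop` fraction of genes with a true sex mean-expression effect get a
#' sex-specific upstream peak whose open sex opposes the expression-up sex;
#' a further `sex_specific_prop` of background peaks are sex-specific with a
#' random direction. Counts are NB with per-sample library factors.
#'
#' @param annotation a [gene_annotation].
#' @param truth_genes per-gene truth table.
#' @param cfg a [sim_config].
#' @param seed seed (default `cfg$seed + 4`).
#' @return list: `peaks` ([peak_count_matrix]), `atac_samples`,
#'   `truth` (per-peak lfc_f_over_m, linked gene).
#' @export
simulate_peaks <- function(annotation, truth_genes, cfg, seed = cfg$seed + 4) {
  pc <- cfg$peaks
  atac_samples <- sample_info(
    c(sprintf("atacM%02d", seq_len(pc$n_per_sex)),
      sprintf("atacF%02d", seq_len(pc$n_per_sex))),
    rep(c(0L, 1L), each = pc$n_per_sex))
  with_seed(seed, {
    tss <- gene_start_site(annotation)
    up <- annotation$strand == "+"
    # peak interval 500 bp wide, centred ~20 kb upstream (BED half-open)
    pstart <- ifelse(up, tss - 20250, tss + 19750)
    gene_peaks <- data.frame(
      peak_id = paste0("peak_", annotation$gene_id),
      chrom = annotation$chrom, start = as.integer(pstart),
      end = as.integer(pstart + 500),
      gene_id = annotation$gene_id, stringsAsFactors = FALSE)
    bg <- data.frame(
      peak_id = sprintf("peak_bg%04d", seq_len(pc$n_background)),
      chrom = "chr1",
      start = as.integer(3.5e6 + (seq_len(pc$n_background) - 1) * 2e4),
      end = as.integer(3.5e6 + (seq_len(pc$n_background) - 1) * 2e4 + 500),
      gene_id = NA_character_, stringsAsFactors = FALSE)
    peaks_df <- rbind(gene_peaks, bg)
    n_peaks <- nrow(peaks_df)

    lfc <- rep(0, n_peaks)
    gi <- match(truth_genes$gene_id, peaks_df$gene_id)
    esc <- truth_genes$escape
    lfc[gi[esc]] <- pc$lfc                      # escape: female-open
    de <- truth_genes$beta2 != 0 & !esc
    linked <- de & stats::runif(nrow(truth_genes)) < pc$link_prop
    lfc[gi[linked]] <- -sign(truth_genes$beta2[linked]) * pc$lfc  # opposing
    bg_idx <- which(is.na(peaks_df$gene_id))
    bg_sex <- bg_idx[stats::runif(length(bg_idx)) < pc$sex_specific_prop]
    lfc[bg_sex] <- sample(c(-1, 1), length(bg_sex), replace = TRUE) * pc$lfc

    lib <- exp(stats::rnorm(nrow(atac_samples), 0, pc$lib_sd))
    base <- exp(stats::rnorm(n_peaks, pc$base_log_mean, 0.5))
    sexv <- atac_samples$sex
    mu <- outer(base, lib) * 2^(outer(lfc, sexv - 0.5))
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / max(cfg$nb_dispersion, 1e-8)),
                     n_peaks, dimnames = list(peaks_df$peak_id,
                                              atac_samples$sample_id))
    list(peaks = peak_count_matrix(counts, peaks_df$chrom, peaks_df$start,
                                   peaks_df$end, atac_samples),
         atac_samples = atac_samples,
         truth = data.frame(peak_id = peaks_df$peak_id,
                            gene_id = peaks_df$gene_id, lfc_f_over_m = lfc,
                            lib_factor = NA, stringsAsFactors = FALSE))
  })
}

#' Simulate a GWAS catalog tagging cohort eQTLs
#'
#' Trait variants are the causal variants of the genes assigned to each
#' trait in the plan (the "BIASED" trait's genes carry sex-aligned
#' interaction effects, "NULLk" traits' genes carry sex-constant effects);
#' LD proxies added during genotype simulation are listed with weaker GWAS
#' p-values so pruning retains the lead variant.
#'
#' @param truth_genes per-gene truth table.
#' @param proxy_map proxy table from [simulate_genotypes].
#' @param genotypes a [genotype_matrix] (for proxy positions).
#' @param cfg a [sim_config].
#' @param seed seed (default `cfg$seed + 5`).
#' @return list: `catalog` ([gwas_catalog]), `truth` (per trait-variant
#'   sex-bias direction).
#' @export
simulate_gwas_catalog <- function(truth_genes, proxy_map, genotypes, cfg,
                                  seed = cfg$seed + 5) {
  tg <- truth_genes[!is.na(truth_genes$trait), , drop = FALSE]
  if (!nrow(tg)) {
    return(list(catalog = gwas_catalog(character(0), character(0),
                                       numeric(0), character(0), integer(0)),
                truth = NULL))
  }
  vids <- tg$causal_variant
  vi <- match(vids, rownames(genotypes$dosage))
  with_seed(seed, {
    gwas_p <- 10^(-stats::runif(nrow(tg), 9, 20))
    cat_df <- data.frame(trait = tg$trait, variant_id = vids, gwas_p = gwas_p,
                         chrom = genotypes$chrom[vi],
                         pos = genotypes$pos[vi], stringsAsFactors = FALSE)
    pm <- proxy_map[proxy_map$variant_id %in% vids, , drop = FALSE]
    if (nrow(pm)) {
      pi <- match(pm$proxy_id, rownames(genotypes$dosage))
      lead <- match(pm$variant_id, cat_df$variant_id)
      cat_df <- rbind(cat_df, data.frame(
        trait = cat_df$trait[lead], variant_id = pm$proxy_id,
        gwas_p = pmin(1, cat_df$gwas_p[lead] * 10^stats::runif(nrow(pm), 1, 3)),
        chrom = genotypes$chrom[pi], pos = genotypes$pos[pi],
        stringsAsFactors = FALSE))
    }
    truth <- data.frame(
      trait = tg$trait, variant_id = vids, gene_id = tg$gene_id,
      bias = ifelse(abs(tg$beta1 + tg$beta3) >= 1.2 * abs(tg$beta1), "female",
                    ifelse(abs(tg$beta1) >= 1.2 * abs(tg$beta1 + tg$beta3),
                           "male", "none")),
      stringsAsFactors = FALSE)
    list(catalog = gwas_catalog(cat_df$trait, cat_df$variant_id,
                                cat_df$gwas_p, cat_df$chrom, cat_df$pos),
         truth = truth)
  })
}

#' Simulate a full cohort with ground truth
#'
#' Runs the gene plan and all component simulators with per-stage seeds
#' derived from `cfg$seed` (`seed + 1 ... seed + 5`), so each stage is
#' independently reproducible.
#'
#' @param cfg a [sim_config].
#' @return list: `samples`, `genotypes`, `expr` (residuals), `counts`,
#'   `annotation`, `ase`, `peaks`, `atac_samples`, `catalog`, `proxy_map`,
#'   `truth` (list: genes, ase, peaks, catalog), `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  plan <- plan_cohort(cfg)
  gt <- simulate_genotypes(cfg, plan)
  ex <- simulate_expression(gt$genotypes, plan$genes, cfg)
  as_ <- simulate_ase(plan$genes, cfg)
  pk <- simulate_peaks(plan$annotation, plan$genes, cfg)
  gw <- simulate_gwas_catalog(plan$genes, gt$proxy_map, gt$genotypes, cfg)
  list(samples = gt$samples, genotypes = gt$genotypes,
       expr = ex$residuals, counts = ex$counts,
       annotation = plan$annotation, ase = as_$ase,
       peaks = pk$peaks, atac_samples = pk$atac_samples,
       catalog = gw$catalog, proxy_map = gt$proxy_map,
       truth = list(genes = plan$genes, ase = as_$truth, peaks = pk$truth,
                    catalog = gw$truth),
       config = cfg)
}
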