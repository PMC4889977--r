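# Simulation-based validation utilities: null calibration, parameter
# recovery, directional X-biology runs and FDR experiments. These drive the
# package's self-checks; cohort dimensions default to the emulated study
# (274 males / 648 females).

#' Null-calibration p-values for a pipeline component
#'
#' Simulates null units for one testing component and returns the vector of
#' nominal p-values, whose empirical exceedance at `alpha` should match
#' `alpha`:
#' * `"interaction"`: genotype-by-sex Wald test with true `b3 = 0`
#'   (genotype and sex effects present) in a 648/274 cohort.
#' * `"dv"`: differential-variance strategy C with per-gene mean shifts but
#'   equal variances, matched 274/274 samples.
#' * `"nb"`: NB exact test on null peaks (common NB rate per peak,
#'   dispersion `alpha_nb`), 10 vs 10 samples with library-size variation.
#' * `"ase"`: ASE GLMM likelihood-ratio test with `delta = 0`, `tau = 0`
#'   (gene-level ASE present through gamma).
#'
#' @param component which null to simulate.
#' @param n_units number of null genes/peaks.
#' @param seed integer seed.
#' @param n_male,n_female cohort sizes for the regression components.
#' @param n_per_sex group size for `"nb"` (samples) and `"ase"`
#'   (heterozygous individuals).
#' @param alpha_nb NB dispersion for `"nb"`.
#' @param lambda_ase read depth for `"ase"`.
#' @return Numeric vector of `n_units` p-values.
#' @export
null_calibration <- function(component = c("interaction", "dv", "nb", "ase"),
                             n_units = 2000, seed = 1,
                             n_male = 274, n_female = 648,
                             n_per_sex = if (component == "nb") 10 else 30,
                             alpha_nb = 0.2, lambda_ase = 50) {
  component <- match.arg(component)
  with_seed(seed, switch(component,
    interaction = {
      sex <- rep(c(0L, 1L), c(n_male, n_female))
      n <- length(sex)
      vapply(seq_len(n_units), function(i) {
        g <- stats::rbinom(n, 2, stats::runif(1, 0.1, 0.5))
        y <- 0.3 * g + 0.2 * sex + stats::rnorm(n)
        rec <- fit_interaction(y, g, sex)
        if (is.null(rec)) NA_real_ else rec$p
      }, numeric(1))
    },
    dv = {
      sex <- rep(c(0L, 1L), each = 274)
      si <- sample_info(sprintf("s%03d", seq_along(sex)), sex)
      shift <- stats::rnorm(n_units)
      vals <- matrix(stats::rnorm(n_units * length(sex)), n_units) +
        outer(shift, sex)
      rownames(vals) <- sprintf("g%04d", seq_len(n_units))
      test_dv(expression_matrix(vals, si), strategy = "C_residual")$p
    },
    nb = {
      sexv <- rep(c(0L, 1L), each = n_per_sex)
      lib <- exp(stats::rnorm(length(sexv), 0, 0.2))
      mu0 <- exp(stats::rnorm(n_units, log(100), 0.5))
      counts <- matrix(stats::rnbinom(n_units * length(sexv),
                                      mu = outer(mu0, lib),
                                      size = 1 / alpha_nb),
                       n_units, dimnames = list(sprintf("p%04d", 1:n_units),
                                                NULL))
      nb_diff_test(counts, sexv)$p
    },
    ase = {
      vapply(seq_len(n_units), function(i) {
        u <- ase_null_unit(n_per_sex, gamma = stats::rnorm(1, 0, 0.3),
                           delta = 0, tau = 0, lambda = lambda_ase)
        fit_ase_glmm(u)$p
      }, numeric(1))
    }))
}

ase_null_unit <- function(n_per_sex, gamma, delta, tau, lambda) {
  n <- 2 * n_per_sex
  sex <- rep(c(0L, 1L), each = n_per_sex)
  h <- sample(c(-1L, 1L), n, TRUE)
  tot <- stats::rpois(n, lambda) + 1L
  p <- stats::plogis(gamma * h + delta * h * sex + stats::rnorm(n, 0, tau))
  alt <- stats::rbinom(n, tot, p)
  data.frame(individual = sprintf("i%03d", seq_len(n)), gene_id = "g",
             ref = tot - alt, alt = alt, n = tot, h = h, sex = sex,
             stringsAsFactors = FALSE)
}

#' Parameter-recovery estimates for a pipeline component
#'
#' Repeatedly simulates data with a known parameter and returns the vector
#' of estimates:
#' * `"interaction"`: `b3` from the genotype-by-sex model (648/274 cohort).
#' * `"pve"`: REML cis heritability with `m` causal-window variants.
#' * `"ase"`: GLMM `delta` (sex-interaction log-odds).
#'
#' @param component which parameter to recover.
#' @param n_reps replicate count.
#' @param truth true parameter value.
#' @param seed integer seed.
#' @param n sample size (`"pve"`), or total cohort from `n_male`/`n_female`.
#' @param m variants in the PVE window.
#' @param n_male,n_female cohort split for `"interaction"`.
#' @param n_per_sex heterozygous individuals per sex for `"ase"`.
#' @return Numeric vector of `n_reps` estimates.
#' @export
parameter_recovery <- function(component = c("interaction", "pve", "ase"),
                               n_reps = 200, truth = 0.3, seed = 1,
                               n = 500, m = 30, n_male = 274, n_female = 648,
                               n_per_sex = 30) {
  component <- match.arg(component)
  with_seed(seed, switch(component,
    interaction = {
      sex <- rep(c(0L, 1L), c(n_male, n_female))
      nn <- length(sex)
      vapply(seq_len(n_reps), function(i) {
        g <- stats::rbinom(nn, 2, stats::runif(1, 0.2, 0.4))
        y <- 0.2 * g + 0.3 * sex + truth * g * sex + stats::rnorm(nn)
        fit_interaction(y, g, sex)$beta3
      }, numeric(1))
    },
    pve = {
      sex <- rep(c(0L, 1L), length.out = n)
      vapply(seq_len(n_reps), function(i) {
        dos <- t(vapply(seq_len(m),
                        function(j) stats::rbinom(n, 2, stats::runif(1, 0.1, 0.5)),
                        numeric(n)))
        rownames(dos) <- paste0("v", seq_len(m))
        g <- genotype_matrix(dos, rep("chr1", m), seq_len(m) * 100L,
                             sample_info(sprintf("s%04d", 1:n), sex))
        Z <- scale(t(dos))
        b <- stats::rnorm(m, 0, sqrt(truth / m))
        y <- drop(Z %*% b) + stats::rnorm(n, 0, sqrt(1 - truth))
        grm <- cis_grm(g, rownames(dos))
        estimate_pve(y, grm, "reml")$pve
      }, numeric(1))
    },
    ase = {
      vapply(seq_len(n_reps), function(i) {
        u <- ase_null_unit(n_per_sex, gamma = 0, delta = truth, tau = 0.2,
                           lambda = 50)
        fit_ase_glmm(u)$delta
      }, numeric(1))
    }))
}

# Manual gene plan for X-vs-autosome experiments: per-class effect mixtures.
xbio_plan <- function(n_auto, n_x, beta1_prop = c(auto = 0.5, x = 0.25),
                      beta1_sd = 0.35,
                      beta3_prop = c(auto = 0, x = 0), beta3_sd = 0.4) {
  n_genes <- n_auto + n_x
  # chunk autosomal genes across chromosome names and keep positions within
  # the 32-bit integer range; 2.5 Mb spacing keeps 1 Mb cis windows disjoint
  per_chr <- 800
  auto_chr <- paste0("chr", (seq_len(n_auto) - 1) %/% per_chr + 1)
  chrom <- c(auto_chr, rep("chrX", n_x))
  idx <- c((seq_len(n_auto) - 1) %% per_chr + 1, seq_len(n_x))
  tss <- 2e6 + (idx - 1) * 2.5e6
  gene_id <- sprintf("gene_%s_%03d", ifelse(chrom == "chrX", "X", "A"),
                     seq_len(n_genes))
  ann <- gene_annotation(gene_id, chrom, as.integer(tss),
                         as.integer(tss + 1e4), rep("+", n_genes))
  is_x_gene <- chrom == "chrX"
  p1 <- ifelse(is_x_gene, beta1_prop["x"], beta1_prop["auto"])
  p3 <- ifelse(is_x_gene, beta3_prop["x"], beta3_prop["auto"])
  genes <- data.frame(
    gene_id = gene_id, chrom = chrom,
    causal_variant = paste0(gene_id, "_v1"),
    beta1 = ifelse(stats::runif(n_genes) < p1,
                   stats::rnorm(n_genes, 0, beta1_sd), 0),
    beta2 = 0,
    beta3 = ifelse(stats::runif(n_genes) < p3,
                   stats::rnorm(n_genes, 0, beta3_sd), 0),
    sigma_m = 1, sigma_f = 1, escape = FALSE, trait = NA_character_,
    stringsAsFactors = FALSE)
  list(annotation = ann, genes = genes)
}

#' Directional X-biology experiment on synthetic truth
#'
#' * `"pve"`: X-linked genes with additive effects under full-dosage male
#'   coding; returns mean male and female PVE across genes (hemizygosity
#'   doubles the male genetic variance, so male PVE should exceed female).
#' * `"eqtl_depletion"`: eQTL-gene rate on X set to half the autosomal rate;
#'   returns the X-vs-autosome chi-squared comparison at FDR 0.05.
#' * `"interaction_qq"`: interaction effects enriched on X; returns the
#'   top-50 QQ tail comparison of X vs autosomal interaction p-values.
#'
#' @param component experiment to run.
#' @param seed integer seed.
#' @param n_male,n_female cohort split.
#' @return A list of summary numbers (see details per component).
#' @export
x_biology_run <- function(component = c("pve", "eqtl_depletion",
                                        "interaction_qq"),
                          seed = 1, n_male = 274, n_female = 648) {
  component <- match.arg(component)
  if (component == "pve") {
    cfg <- sim_config(n_male = n_male, n_female = n_female, seed = seed)
    plan <- with_seed(seed, xbio_plan(2, 40, beta1_prop = c(auto = 1, x = 1),
                                      beta1_sd = 0.3))
    plan$genes$beta1 <- with_seed(seed + 7,
                                  0.25 * sign(stats::rnorm(nrow(plan$genes))))
    gt <- simulate_genotypes(cfg, plan)
    ex <- simulate_expression(gt$genotypes, plan$genes, cfg)
    pv <- pve_by_sex(gt$genotypes, ex$residuals, plan$annotation, seed = seed)
    px <- pv[grepl("_X_", pv$gene_id), ]
    return(list(mean_m = mean(px$pve[px$stratum == "male"]),
                mean_f = mean(px$pve[px$stratum == "female"])))
  }
  if (component == "eqtl_depletion") {
    cfg <- sim_config(n_male = n_male, n_female = n_female,
                      variants_per_gene = 3, seed = seed)
    plan <- with_seed(seed, xbio_plan(1350, 650,
                                      beta1_prop = c(auto = 0.5, x = 0.25)))
    gt <- simulate_genotypes(cfg, plan)
    ex <- simulate_expression(gt$genotypes, plan$genes, cfg)
    eq <- map_cis_eqtl(gt$genotypes, ex$residuals, plan$annotation, "additive")
    chrom <- plan$annotation$chrom[match(eq$summary$gene_id,
                                         plan$annotation$gene_id)]
    dep <- xa_eqtl_depletion(eq$summary, chrom, fdr_grid = 0.05)
    return(list(prop_x = dep$prop_x, prop_auto = dep$prop_auto, p = dep$p))
  }
  cfg <- sim_config(n_male = n_male, n_female = n_female,
                    variants_per_gene = 3, seed = seed)
  plan <- with_seed(seed, xbio_plan(300, 150,
                                    beta1_prop = c(auto = 0.3, x = 0.3),
                                    beta3_prop = c(auto = 0.02, x = 0.4),
                                    beta3_sd = 0.5))
  gt <- simulate_genotypes(cfg, plan)
  ex <- simulate_expression(gt$genotypes, plan$genes, cfg)
  ix <- map_cis_eqtl(gt$genotypes, ex$residuals, plan$annotation,
                     "interaction")
  xi <- ix$records$gene_id %in% plan$genes$gene_id[plan$genes$chrom == "chrX"]
  tr <- qq_enrichment(ix$records$p[xi], ix$records$p[!xi], top_k = 50)
  list(p = tr$p_value)
}

#' Realized FDR of the Bonferroni-then-BH gene-level procedure
#'
#' Each replicate simulates `n_genes` genes (`frac_true` of them with a real
#' causal variant among `n_variants` tested), maps additively, and records
#' the false-discovery proportion among genes with gene-level q < `q_thr`.
#'
#' @param n_reps replicates.
#' @param n_genes,n_variants,frac_true,beta,n simulation dimensions.
#' @param q_thr gene-level q threshold.
#' @param seed integer seed.
#' @return data.frame per replicate: discoveries, false discoveries, fdp.
#' @export
fdr_calibration_run <- function(n_reps = 50, n_genes = 200, n_variants = 10,
                                frac_true = 0.1, beta = 0.4, n = 300,
                                q_thr = 0.05, seed = 1) {
  with_seed(seed, {
    sex <- rep(c(0L, 1L), length.out = n)
    out <- lapply(seq_len(n_reps), function(r) {
      true <- stats::runif(n_genes) < frac_true
      recs <- lapply(seq_len(n_genes), function(gi) {
        G <- vapply(seq_len(n_variants),
                    function(j) stats::rbinom(n, 2, stats::runif(1, 0.1, 0.5)),
                    numeric(n))
        y <- stats::rnorm(n) + if (true[gi]) beta * G[, 1] else 0
        ps <- vapply(seq_len(n_variants), function(j) {
          rec <- fit_additive(y, G[, j], sex, "joint")
          if (is.null(rec)) NA_real_ else rec$p
        }, numeric(1))
        data.frame(gene_id = sprintf("g%03d", gi),
                   variant_id = sprintf("v%02d", seq_len(n_variants)),
                   p = ps)
      })
      s <- gene_level_fdr(do.call(rbind, recs))
      disc <- s$q < q_thr
      gi <- match(s$gene_id, sprintf("g%03d", seq_len(n_genes)))
      n_disc <- sum(disc)
      n_false <- sum(disc & !true[gi])
      data.frame(rep = r, n_disc = n_disc, n_false = n_false,
                 fdp = if (n_disc) n_false / n_disc else 0)
    })
    do.call(rbind, out)
  })
}
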