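test_that("cis window boundaries follow the TSS-1Mb / TES+1Mb rule", {
  ann <- gene_annotation("g1", "chr1", 2000000L, 2010000L, "+")
  pos <- c(999999L, 1000001L, 2005000L, 3009999L, 3010001L)
  dos <- matrix(rep(c(0, 1, 2, 1), 5), 5, byrow = TRUE,
                dimnames = list(paste0("v", 1:5), NULL))
  g <- gm_from(dos, rep("chr1", 5), pos, c(0L, 0L, 1L, 1L))
  pr <- cis_pairs(ann, g)
  expect_setequal(pr$variant_id, c("v2", "v3", "v4"))
  # window 0 keeps only intragenic variants
  pr0 <- cis_pairs(ann, g, window = 0)
  expect_equal(pr0$variant_id, "v3")
  # different chromosome is never cis
  g2 <- gm_from(dos, rep("chr2", 5), pos, c(0L, 0L, 1L, 1L))
  expect_equal(nrow(cis_pairs(ann, g2)), 0)
})

test_that("additive and interaction OLS match the normal-equation oracle", {
  set.seed(3)
  n <- 50
  g <- rbinom(n, 2, 0.4); s <- rbinom(n, 1, 0.5)
  y <- 0.5 + 0.3 * g - 0.2 * s + rnorm(n)
  rec <- fit_additive(y, g, s, "joint")
  o <- oracle_ols(cbind(1, g, s), y)
  expect_equal(rec$beta1, unname(o$beta[2]), tolerance = 1e-10)
  expect_equal(rec$beta2, unname(o$beta[3]), tolerance = 1e-10)
  expect_equal(rec$se1, unname(o$se[2]), tolerance = 1e-10)
  expect_equal(rec$mu, unname(o$beta[1]), tolerance = 1e-10)
  # reference implementation agreement for the p-value
  lmfit <- summary(lm(y ~ g + s))
  expect_equal(rec$p, lmfit$coefficients["g", 4], tolerance = 1e-10)

  reci <- fit_interaction(y, g, s)
  oi <- oracle_ols(cbind(1, g, s, g * s), y)
  expect_equal(c(reci$mu, reci$beta1, reci$beta2, reci$beta3), unname(oi$beta),
               tolerance = 1e-10)
  expect_equal(reci$se3, unname(oi$se[4]), tolerance = 1e-10)

  # noise-free generative inputs return exact coefficients
  y2 <- 2 * g
  rec2 <- fit_additive(y2, g, s, "joint")
  expect_equal(rec2$beta1, 2, tolerance = 1e-9)
  expect_lt(rec2$p, 1e-12)
  y3 <- g * s
  rec3 <- fit_interaction(y3, g, s)
  expect_equal(rec3$beta3, 1, tolerance = 1e-9)
  expect_equal(rec3$beta1, 0, tolerance = 1e-9)
})

test_that("covariate/PC residualization removes known structure", {
  set.seed(9)
  n <- 60
  si <- sample_info(sprintf("s%02d", 1:n), rbinom(n, 1, 0.5))
  cov_ <- cbind(batch = rnorm(n))
  Y <- matrix(rnorm(20 * n), 20, dimnames = list(paste0("g", 1:20), si$sample_id))
  Y <- Y + outer(rnorm(20, 0, 2), cov_[, 1])
  expr <- expression_matrix(Y, si)
  r <- residualize_expression(expr, covariates = cov_)
  expect_equal(r$kind, "residuals")
  # every gene is now orthogonal to the covariate and centred
  expect_lt(max(abs(r$values %*% cov_)), 1e-10)
  expect_lt(max(abs(rowMeans(r$values))), 1e-10)
  # PC removal matches explicit projection on the leading component
  r2 <- residualize_expression(expr, n_pcs = 2)
  pcs <- prcomp(t(Y))$x[, 1:2]
  expect_lt(max(abs(r2$values %*% pcs)), 1e-8)
  # robust SEs: agree with the sandwich reference implementation
  g <- rbinom(n, 2, 0.4); y <- 0.3 * g + rnorm(n) * (1 + g)
  rec <- fit_additive(y, g, si$sex, "joint", robust = TRUE)
  fm <- lm(y ~ g + si$sex)
  se_hc0 <- sqrt(diag(sandwich::vcovHC(fm, type = "HC0")))
  expect_equal(rec$se1, unname(se_hc0["g"]), tolerance = 1e-8)
})

test_that("stratified fits drop the sex column and subset samples", {
  set.seed(4)
  n <- 80
  g <- rbinom(n, 2, 0.3); s <- rep(c(0L, 1L), each = n / 2)
  y <- 0.4 * g + 0.8 * g * s + rnorm(n, 0, 0.3)
  rm_ <- fit_additive(y, g, s, "male")
  rf <- fit_additive(y, g, s, "female")
  expect_equal(rm_$n, 40); expect_equal(rf$n, 40)
  expect_true(is.na(rm_$beta2))
  expect_gt(rf$beta1, rm_$beta1)   # female effect includes the interaction
  # too-few samples or monomorphic genotype refuse to fit
  expect_null(fit_additive(y[1:10], g[1:10], s[1:10], "joint", min_n = 30))
  expect_null(fit_additive(y, rep(1, n), s, "joint"))
})

test_that("collinearity filter drops rank-deficient genotype/sex designs", {
  s <- rep(c(0, 1), each = 10)
  expect_false(collinearity_filter(s * 2, s)$keep)       # g identical to s
  expect_false(collinearity_filter(rep(1, 20), s)$keep)  # constant g
  expect_equal(collinearity_filter(rep(1, 20), s)$rank, 2)
  set.seed(5)
  expect_true(collinearity_filter(rbinom(20, 2, 0.5), s)$keep)
  # near-collinear within tolerance is dropped
  expect_false(collinearity_filter(s + 1e-12, s)$keep)
})

test_that("gene-level FDR applies Bonferroni-then-BH with deterministic ties", {
  recs <- data.frame(
    gene_id = c(rep("gB", 10), "gA", "gC", "gC"),
    variant_id = c(paste0("v", 10:1), "w1", "u2", "u1"),
    p = c(0.004, rep(0.5, 9), 0.02, 0.03, 0.03))
  s <- gene_level_fdr(recs)
  expect_equal(s$gene_id, c("gA", "gB", "gC"))
  expect_equal(s$n_tests, c(1L, 10L, 2L))
  expect_equal(s$bonf_p[s$gene_id == "gB"], 0.04)
  expect_equal(s$bonf_p[s$gene_id == "gA"], 0.02)   # single test: nominal
  # tie on p resolved lexicographically
  expect_equal(s$best_variant[s$gene_id == "gC"], "u1")
  expect_equal(s$q, bh_fdr(s$bonf_p))
})

test_that("interaction scan respects per-sex MAF and restriction lists", {
  co <- simulate_cohort(tiny_cfg(seed = 23))
  ix <- map_cis_eqtl(co$genotypes, co$expr, co$annotation, "interaction")
  expect_true(all(ix$records$model == "interaction"))
  expect_true(all(ix$records$n <= ncol(co$expr$values)))
  # restriction to one variant per gene shrinks the test count
  restr <- setNames(as.list(co$truth$genes$causal_variant),
                    co$truth$genes$gene_id)
  ixr <- map_cis_eqtl(co$genotypes, co$expr, co$annotation, "interaction",
                      restrict_variants = restr)
  expect_true(all(ixr$summary$n_tests == 1))
  expect_true(all(ixr$records$variant_id %in% unlist(restr)))
})

test_that("results are invariant under sample-order permutation", {
  co <- simulate_cohort(tiny_cfg(seed = 29))
  perm <- sample(ncol(co$expr$values))
  si <- sample_info(co$samples$sample_id[perm], co$samples$sex[perm])
  g2 <- genotype_matrix(co$genotypes$dosage[, perm], co$genotypes$chrom,
                        co$genotypes$pos, si, co$genotypes$x_coding)
  e2 <- expression_matrix(co$expr$values[, perm], si)
  a <- map_cis_eqtl(co$genotypes, co$expr, co$annotation, "additive")
  b <- map_cis_eqtl(g2, e2, co$annotation, "additive")
  expect_equal(a$summary, b$summary, tolerance = 1e-12)
})

test_that("effect-size comparison folds, bins and the QQ-tail test behave", {
  set.seed(6)
  ra <- data.frame(beta1 = rnorm(200, 0, 0.5))
  rb <- data.frame(beta1 = rnorm(200, 0, 0.5))
  out <- effect_size_compare(ra, rb)
  expect_equal(out$fold[1], 1, tolerance = 0.2)
  expect_gt(out$p[1], 0.001)
  # quantile bins partition the records into near-equal fifths
  out5 <- effect_size_compare(ra, rb, score_a = rnorm(200), score_b = rnorm(200))
  expect_equal(sum(out5$n_a[-1]), 200)
  # pooled-score quantile edges split the pooled records into exact fifths
  expect_true(all(abs(out5$n_a[-1] + out5$n_b[-1] - 80) <= 1))
  # sparse bins report NA
  outs <- effect_size_compare(ra[1:4, , drop = FALSE], rb)
  expect_true(is.na(outs$fold[1]))

  expect_error(qq_enrichment(runif(100), runif(100), top_k = 1), ">= 2")
  expect_error(qq_enrichment(runif(10), runif(100), top_k = 50), "exceeds")
  p_match <- qq_enrichment(runif(500), runif(500), top_k = 50)$p_value
  expect_gt(p_match, 1e-4)
})
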