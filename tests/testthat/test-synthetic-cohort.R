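test_that("genotype simulation is deterministic and respects allele frequencies", {
  cfg <- tiny_cfg(seed = 5)
  g1 <- simulate_genotypes(cfg)$genotypes
  g2 <- simulate_genotypes(cfg)$genotypes
  expect_identical(g1$dosage, g2$dosage)

  # degenerate maf_range pins every frequency at 0.5
  cfg2 <- tiny_cfg(seed = 5, maf_range = c(0.5, 0.5),
                   n_male = 2000, n_female = 2000, n_genes_auto = 2,
                   n_genes_x = 1, variants_per_gene = 2)
  g <- simulate_genotypes(cfg2)$genotypes
  auto <- g$dosage[!is_x_rows(g), g$samples$sex == 1, drop = FALSE]
  # Binomial(2, 0.5) mean 1, sd 1/sqrt(2); 3-sigma band on the row mean
  n <- ncol(auto)
  expect_true(all(abs(rowMeans(auto) - 1) < 3 * sqrt(0.5 / n)))
  # male X dosages honour the coding
  xm <- g$dosage[is_x_rows(g), g$samples$sex == 0, drop = FALSE]
  expect_true(all(xm %in% c(0, 2)))
})

test_that("expression generator reproduces the regression arithmetic exactly at sigma = 0", {
  cfg <- tiny_cfg(seed = 9)
  gt <- simulate_genotypes(cfg)
  truth <- data.frame(gene_id = "gA", chrom = "chr1",
                      causal_variant = rownames(gt$genotypes$dosage)[1],
                      beta1 = 0.2, beta2 = 0.3, beta3 = 0.5,
                      sigma_m = 1e-12, sigma_f = 1e-12, escape = FALSE,
                      trait = NA, stringsAsFactors = FALSE)
  ex <- simulate_expression(gt$genotypes, truth, cfg)
  y <- ex$residuals$values[1, ]
  g <- gt$genotypes$dosage[truth$causal_variant, ]
  s <- gt$samples$sex
  expect_equal(unname(y), unname(0.2 * g + 0.3 * s + 0.5 * g * s),
               tolerance = 1e-9)
})

test_that("sex-specific residual-variance ratios are recovered at scale", {
  cfg <- tiny_cfg(seed = 2, n_male = 4000, n_female = 4000)
  gt <- simulate_genotypes(cfg)
  truth <- data.frame(gene_id = "gA", chrom = "chr1",
                      causal_variant = rownames(gt$genotypes$dosage)[1],
                      beta1 = 0, beta2 = 0, beta3 = 0,
                      sigma_m = 1, sigma_f = 2, escape = FALSE, trait = NA,
                      stringsAsFactors = FALSE)
  ex <- simulate_expression(gt$genotypes, truth, cfg)
  s <- gt$samples$sex
  ratio <- var(ex$residuals$values[1, s == 1]) /
    var(ex$residuals$values[1, s == 0])
  expect_gt(ratio, 3.4); expect_lt(ratio, 4.7)
  # all effects zero: sex means equal within sampling error
  dm <- mean(ex$residuals$values[1, s == 1]) -
    mean(ex$residuals$values[1, s == 0])
  expect_lt(abs(dm), 3 * sqrt(1 / 4000 + 4 / 4000))
})

test_that("ASE generator hits its logistic target fractions", {
  cfg <- tiny_cfg(seed = 3)
  # delta = 1, s = 1, h = +1, everything else zero: alt fraction 0.731
  cfg$ase <- list(n_genes = 1, n_het_per_sex = 3000, lambda = 80,
                  gamma_sd = 1e-12, delta_prop = 1, delta = 1, tau = 1e-12)
  truth_genes <- data.frame(gene_id = "gA", stringsAsFactors = FALSE)
  sim <- simulate_ase(truth_genes, cfg)
  d <- sim$ase
  fem_pos <- d$sex == 1 & d$h == 1
  frac <- sum(d$alt_count[fem_pos]) /
    sum(d$alt_count[fem_pos] + d$ref_count[fem_pos])
  expect_equal(frac, plogis(1), tolerance = 0.01)
  # null gene: pooled alt fraction near 0.5
  cfg$ase$delta_prop <- 0; cfg$ase$gamma_sd <- 1e-12
  sim0 <- simulate_ase(truth_genes, cfg)
  frac0 <- sum(sim0$ase$alt_count) /
    sum(sim0$ase$alt_count + sim0$ase$ref_count)
  expect_equal(frac0, 0.5, tolerance = 0.01)
  # determinism
  expect_identical(simulate_ase(truth_genes, cfg)$ase, sim0$ase)
})

test_that("simulated cohort files satisfy the dataio round-trip property", {
  co <- simulate_cohort(tiny_cfg(seed = 13))
  dir <- withr::local_tempdir()
  write_vcf(co$genotypes, file.path(dir, "g.vcf"))
  g2 <- read_vcf(file.path(dir, "g.vcf"), co$samples)
  expect_equal(g2$dosage, co$genotypes$dosage)
  write_expression(co$expr, file.path(dir, "e.tsv"))
  e2 <- read_expression(file.path(dir, "e.tsv"), co$samples)
  expect_equal(e2$values, co$expr$values, tolerance = 1e-12)
  write_peaks(co$peaks, file.path(dir, "p.bed"), file.path(dir, "p.tsv"))
  p2 <- read_peaks(file.path(dir, "p.bed"), file.path(dir, "p.tsv"),
                   co$atac_samples)
  expect_equal(p2$counts, co$peaks$counts)
  write_ase(co$ase, file.path(dir, "a.tsv"))
  expect_equal(as.data.frame(read_ase(file.path(dir, "a.tsv"))),
               as.data.frame(co$ase))
})

test_that("library-size shifts propagate to size factors; empty catalog allowed", {
  co <- simulate_cohort(tiny_cfg(seed = 17))
  counts <- co$peaks$counts
  counts[, 1] <- counts[, 1] * 2L
  sf <- size_factors(counts)
  sf0 <- size_factors(co$peaks$counts)
  expect_equal(unname(sf[1] / sf0[1] / (sf[2] / sf0[2])), 2, tolerance = 0.1)
  # no trait genes -> empty catalog, no error
  expect_equal(nrow(co$catalog), 0)
})
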