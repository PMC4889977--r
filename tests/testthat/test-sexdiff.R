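test_that("match_subsample balances the sexes deterministically", {
  sex <- rep(c(0L, 1L), c(5, 9))
  idx <- match_subsample(sex, seed = 3)
  expect_equal(sum(sex[idx] == 0), 5)
  expect_equal(sum(sex[idx] == 1), 5)
  expect_identical(idx, match_subsample(sex, seed = 3))
  expect_false(identical(idx, match_subsample(sex, seed = 4)))
  # DGN-like imbalance: 274 male + 274 of 648 females
  sex2 <- rep(c(0L, 1L), c(274, 648))
  idx2 <- match_subsample(sex2, seed = 1)
  expect_equal(as.vector(table(sex2[idx2])), c(274, 274))
  # equal groups: identity
  expect_equal(match_subsample(rep(c(0L, 1L), 4), 1), 1:8)
  expect_error(match_subsample(rep(0L, 5), 1), "both sexes")
})

test_that("quantile normalization maps midranks to normal quantiles", {
  got <- quantile_normalize_to_normal(c(5, 1, 9))
  expect_equal(got, qnorm(c(0.5, 1 / 6, 5 / 6)), tolerance = 1e-12)
  expect_equal(got[3], 0.9674216, tolerance = 1e-6)
  set.seed(8)
  x <- rnorm(100)
  expect_equal(cor(quantile_normalize_to_normal(x), x, method = "spearman"), 1)
  expect_error(quantile_normalize_to_normal(rep(2, 5)), "constant")
  # ties share midranks, preserving label-exchange symmetry
  expect_equal(quantile_normalize_to_normal(c(1, 1, 2))[1],
               quantile_normalize_to_normal(c(1, 1, 2))[2])
})

test_that("DV strategies recover variance differences and gate on normality", {
  set.seed(101)
  n <- 274
  sex <- rep(c(0L, 1L), each = n)
  si <- sample_info(sprintf("s%03d", seq_along(sex)), sex)
  # gene 1: sigma_f = 2 sigma_m; gene 2: null; gene 3: exponential tails
  vals <- rbind(g1 = c(rnorm(n, 0, 1), rnorm(n, 0, 2)),
                g2 = rnorm(2 * n),
                g3 = c(rexp(n), rexp(n)))
  expr <- expression_matrix(vals, si)
  dvA <- test_dv(expr, strategy = "A_F")
  expect_lt(dvA$p[dvA$gene_id == "g1"], 1e-6)
  expect_equal(dvA$direction[dvA$gene_id == "g1"], "female")
  expect_equal(dvA$branch, rep("F", 3))
  dvB <- test_dv(expr, strategy = "B_gated")
  expect_equal(dvB$branch[dvB$gene_id == "g3"], "BF")  # Shapiro rejects
  expect_equal(dvB$branch[dvB$gene_id == "g2"], "F")
  # per-sex gate scope is exposed and changes nothing for these genes
  dvB2 <- test_dv(expr, strategy = "B_gated", gate_scope = "per_sex")
  expect_equal(dvB2$branch[dvB2$gene_id == "g3"], "BF")
  expect_error(test_dv(expression_matrix(vals[, 1:4], sample_info(
    si$sample_id[1:4], sex[1:4])), strategy = "A_F"), ">= 3")
})

test_that("residual DV strategy is immune to pure mean shifts", {
  set.seed(102)
  n <- 150
  sex <- rep(c(0L, 1L), each = n)
  si <- sample_info(sprintf("s%03d", seq_along(sex)), sex)
  # strong DE, no DV: strategy C must not flag
  vals <- matrix(rnorm(2 * n * 400) + rep(2 * sex, each = 400), 400,
                 dimnames = list(sprintf("g%03d", 1:400), si$sample_id))
  expr <- expression_matrix(vals, si)
  dvC <- test_dv(expr, strategy = "C_residual")
  expect_gt(min(dvC$q), 0.05)
  # Kolmogorov check that C-strategy null p-values are roughly uniform
  expect_gt(ks.test(dvC$p, "punif")$p.value, 0.01)
  # the literal per-gene rank-normal pretransform is valid but conservative:
  # mapping each gene onto fixed normal scores pins the pooled variance
  dvCg <- test_dv(expr, strategy = "C_residual", qn = "gene")
  expect_lte(mean(dvCg$p < 0.05), 0.05)
})

test_that("differential mean expression flags simulated sex effects", {
  set.seed(103)
  n <- 100
  sex <- rep(c(0L, 1L), each = n)
  si <- sample_info(sprintf("s%03d", seq_along(sex)), sex)
  vals <- rbind(g1 = rnorm(2 * n, 0, 0.5) + 1 * sex,
                g2 = rnorm(2 * n),
                g3 = rep(3, 2 * n))
  expr <- expression_matrix(vals, si)
  de <- test_de(expr, method = "welch")
  expect_lt(de$q[de$gene_id == "g1"], 0.05)
  expect_equal(de$direction[de$gene_id == "g1"], "female")
  expect_equal(de$effect[de$gene_id == "g1"], 1, tolerance = 0.2)
  expect_equal(de$p[de$gene_id == "g3"], 1)   # constant gene
  expect_error(test_de(expr, method = "nb"), "counts")
})

test_that("NB differential expression works on the count matrix", {
  co <- simulate_cohort(tiny_cfg(seed = 31, n_male = 30, n_female = 30))
  de <- test_de(co$counts, method = "nb")
  expect_equal(nrow(de), nrow(co$counts$values))
  expect_true(all(de$p > 0 & de$p <= 1))
  b2 <- co$truth$genes$beta2
  # strongest true sex effect should rank far above the average null gene
  if (any(b2 != 0)) {
    top <- which.max(abs(b2))
    expect_lt(de$p[top], median(de$p[b2 == 0]))
  }
})

test_that("X/autosome proportion and DV-DE overlap tests agree with oracles", {
  flags <- c(rep(TRUE, 10), rep(FALSE, 90), rep(TRUE, 60), rep(FALSE, 940))
  chrom <- rep(c("chrX", "chr1"), c(100, 1000))
  tr <- xa_proportion_test(flags, chrom)
  expect_equal(attr(tr, "prop_x"), 0.10)
  expect_equal(attr(tr, "prop_auto"), 0.06)
  ft <- fisher.test(rbind(c(10, 90), c(60, 940)), alternative = "greater")
  expect_equal(tr$p_value, ft$p.value, tolerance = 1e-12)
  expect_error(xa_proportion_test(flags, rep("chr1", 1100)), "both")

  set.seed(104)
  a <- runif(500) < 0.1; b <- runif(500) < 0.2
  expect_gt(dv_de_overlap_test(a, b)$p_value, 1e-4)   # independent flags
  expect_lt(dv_de_overlap_test(b, b)$p_value, 1e-10)  # perfectly nested
  expect_warning(tr0 <- dv_de_overlap_test(rep(FALSE, 10), b[1:10]),
                 "degenerate")
  expect_equal(tr0$p_value, 1)
})
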