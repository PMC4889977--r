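test_that("size factors follow median-of-ratios with the documented fallbacks", {
  counts <- matrix(c(10, 20, 30, 40, 100, 7), 3,
                   dimnames = list(paste0("p", 1:3), c("a", "b")))
  counts[, 2] <- counts[, 1] * 2
  sf <- size_factors(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # identical samples -> unit factors; single sample -> 1
  same <- cbind(a = c(3, 9, 1), b = c(3, 9, 1))
  rownames(same) <- paste0("p", 1:3)
  expect_equal(unname(size_factors(same)), c(1, 1))
  expect_equal(unname(size_factors(same[, 1, drop = FALSE])), 1)
  # agreement with the reference implementation on random data
  set.seed(1)
  m <- matrix(rnbinom(500, mu = 50, size = 5) + 1, 50)
  rownames(m) <- paste0("p", 1:50)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
  # global rescaling cancels against the reference: factors unchanged,
  # while scaling one sample scales only its factor
  expect_equal(unname(size_factors(m * 3)), unname(size_factors(m)),
               tolerance = 1e-10)
  m2 <- m; m2[, 1] <- m2[, 1] * 4
  expect_equal(unname(size_factors(m2)[1] / size_factors(m)[1]),
               4 * unname(size_factors(m2)[2] / size_factors(m)[2]),
               tolerance = 1e-10)
  zero <- matrix(c(0L, 5L, 5L, 0L), 2, dimnames = list(c("p1", "p2"), NULL))
  expect_warning(size_factors(zero), "library-size")
})

test_that("dispersion estimation recovers Poisson and NB truths", {
  set.seed(2)
  groups <- rep(c(0, 1), each = 10)
  pois <- matrix(rpois(3000 * 20, 100), 3000)
  dp <- estimate_dispersion(pois, groups, sharing = "raw")
  expect_lt(median(dp$alpha, na.rm = TRUE), 0.003)
  nb <- matrix(rnbinom(3000 * 20, mu = 100, size = 5), 3000)
  dn <- estimate_dispersion(nb, groups, sharing = "raw")
  med <- median(dn$alpha, na.rm = TRUE)
  expect_gt(med, 0.1); expect_lt(med, 0.35)
  # trend sharing pools information across peaks
  dt <- estimate_dispersion(nb, groups, sharing = "trend")
  expect_lt(sd(dt$alpha, na.rm = TRUE), sd(dn$alpha, na.rm = TRUE))
  const <- matrix(5L, 4, 20)
  expect_equal(unique(estimate_dispersion(const, groups, sharing = "raw")$alpha), 0)
  expect_error(estimate_dispersion(nb[, 1:3], rep(c(0, 1), c(1, 2))), ">= 2")
})

test_that("NB exact test equals naive enumeration on small totals", {
  sf <- c(0.9, 1.1, 1.0, 1.3, 0.8, 1.0)
  groups <- rep(c(0, 1), each = 3)
  set.seed(3)
  for (alpha in c(0, 0.1, 0.5)) {
    for (rep_ in 1:20) {
      k <- rpois(6, 5)
      r <- nb_test(k, groups, sf, alpha)
      o <- oracle_nb_exact(sum(k[1:3]), sum(k), sf, groups, alpha)
      expect_equal(r$p, o, tolerance = 1e-12)
    }
  }
  # identical groups sit at the modal split
  kk <- rep(10L, 6)
  expect_equal(nb_test(kk, groups, rep(1, 6), 0.2)$p, 1, tolerance = 1e-9)
})

test_that("swapping sex labels flips fold signs and preserves p", {
  set.seed(4)
  counts <- matrix(rnbinom(200 * 20, mu = 80, size = 5), 200,
                   dimnames = list(sprintf("p%03d", 1:200), NULL))
  sex <- rep(c(0L, 1L), each = 10)
  a <- nb_diff_test(counts, sex)
  b <- nb_diff_test(counts, 1L - sex)
  expect_equal(a$p, b$p, tolerance = 1e-9)
  expect_equal(a$log2_fold, -b$log2_fold, tolerance = 1e-9)
})

test_that("peak-gene links respect the 40-kb strand-oriented upstream rule", {
  si <- sample_info(c("a", "b", "c", "d"), c(0L, 0L, 1L, 1L))
  ann <- gene_annotation(c("gplus", "gminus"), c("chr1", "chr1"),
                         tss = c(100000L, 500000L), tes = c(110000L, 490000L),
                         strand = c("+", "-"))
  # BED peaks: 39 kb and 41 kb upstream of gplus; 39 kb downstream-of-start
  # (i.e. genomically above) for the minus-strand gene
  counts <- matrix(5L, 4, 4,
                   dimnames = list(c("near", "far", "minus_up", "minus_wrong"),
                                   si$sample_id))
  pk <- peak_count_matrix(counts, rep("chr1", 4),
                          start = c(100000L - 39000L, 100000L - 41500L,
                                    500000L + 38000L, 500000L - 5000L),
                          end = c(100000L - 38500L, 100000L - 41000L,
                                  500000L + 38500L, 500000L - 4500L), si)
  lk <- peak_gene_link(pk, ann, upstream_bp = 40000)
  expect_true(any(lk$peak_id == "near" & lk$gene_id == "gplus"))
  expect_false("far" %in% lk$peak_id)
  expect_true(any(lk$peak_id == "minus_up" & lk$gene_id == "gminus"))
  expect_false(any(lk$peak_id == "minus_wrong" & lk$gene_id == "gminus"))
  # zero window keeps only TSS-overlapping peaks
  lk0 <- peak_gene_link(pk, ann, upstream_bp = 0)
  expect_equal(nrow(lk0), 0)
  # genomic (non-strand-oriented) mode looks left of the stored tss
  lkg <- peak_gene_link(pk, ann, upstream_bp = 40000, strand_oriented = FALSE)
  expect_false("minus_up" %in% lkg$peak_id)
})

test_that("integration enrichment detects built-in peak-expression coupling", {
  co <- simulate_cohort(tiny_cfg(seed = 43, n_genes_auto = 30, n_genes_x = 10,
                                 beta2 = list(prop = 0.5, sd = 0.8),
                                 peaks = list(n_background = 30, n_per_sex = 8,
                                              lfc = 2, sex_specific_prop = 0.05,
                                              link_prop = 1,
                                              base_log_mean = log(150),
                                              lib_sd = 0.2)))
  at <- atac_sex_test(co$peaks)
  lk <- peak_gene_link(co$peaks, co$annotation)
  truth <- co$truth$genes
  flags <- setNames(truth$beta2 != 0, truth$gene_id)
  dirs <- setNames(ifelse(truth$beta2 >= 0, "female", "male"), truth$gene_id)
  res <- integration_enrichment(at, flags, lk, gene_dir = dirs)
  expect_true(any(res$enrichment$or > 1, na.rm = TRUE))
  # built-in coupling opposes directions, so the directional test fires
  expect_false(is.null(res$directional))
  expect_error(integration_enrichment(at, flags, lk[0, ]), "empty")
})

test_that("escape enrichment uses a floored top decile of X peaks", {
  co <- simulate_cohort(tiny_cfg(seed = 47, n_genes_x = 25,
                                 escape_fraction = 0.3, escape_shift = 1))
  at <- atac_sex_test(co$peaks)
  lk <- peak_gene_link(co$peaks, co$annotation)
  esc <- co$truth$genes$gene_id[co$truth$genes$escape]
  tr <- escape_enrichment(at, esc, lk, top_fraction = 0.1)
  expect_s3_class(tr, "sexqtl_test")
  # 25 X gene peaks -> floor(2.5) = 2 top peaks
  n_x <- sum(at$chrom == "chrX")
  expect_equal(floor(n_x * 0.1), 2)
  expect_error(escape_enrichment(at, character(0), lk), "empty")
})
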