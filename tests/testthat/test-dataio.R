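test_that("VCF round-trip preserves dosages including male X coding", {
  set.seed(1)
  sex <- c(0L, 0L, 1L, 1L, 1L)
  dos <- rbind(v1 = c(0, 1, 2, 1, 0),          # autosomal
               v2 = c(2, 0, 1, 2, 0),          # chrX, males in {0,2}
               v3 = c(0, 2, 0, 1, NA))         # chrX with missing female
  g <- gm_from(dos, c("chr1", "chrX", "chrX"), c(100L, 200L, 300L), sex)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, path)
  si <- g$samples
  g2 <- read_vcf(path, si)
  expect_equal(g2$dosage, g$dosage)
  expect_equal(g2$chrom, g$chrom)
  expect_equal(g2$pos, g$pos)
  # haploid coding of the same file halves male X dosages
  g3 <- read_vcf(path, si, x_coding = "haploid")
  expect_equal(unname(g3$dosage["v2", 1:2]), c(1, 0))
  expect_equal(unname(g3$dosage["v2", 3:5]), c(1, 2, 0))
})

test_that("read_vcf flags unknown samples and impossible male X hets", {
  lines <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsA\tsB",
             "chrX\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/1")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, path)
  si <- sample_info(c("sA", "sB"), c(0L, 1L))
  expect_warning(g <- read_vcf(path, si), "heterozygous male chrX")
  expect_true(is.na(g$dosage["v1", "sA"]))
  expect_equal(unname(g$dosage["v1", "sB"]), 1)  # female het counts alleles
  expect_equal(g$n_male_het_x, 1L)
  expect_error(read_vcf(path, sample_info("sA", 0L)), "without sex")
})

test_that("sex-aware MAF counts one allele per male on chrX", {
  # autosome: alt alleles 5 of 8
  expect_equal(sex_aware_maf(c(0, 1, 2, 2), c(0, 1, 0, 1)), 3 / 8)
  # chrX full_dosage: male alt (2), male ref (0), female het (1), homref (0)
  expect_equal(sex_aware_maf(c(2, 0, 1, 0), c(0, 0, 1, 1), chrx = TRUE), 2 / 6)
  expect_equal(sex_aware_maf(c(1, 0, 1, 0), c(0, 0, 1, 1), chrx = TRUE,
                             x_coding = "haploid"), 2 / 6)
  expect_equal(sex_aware_maf(c(0, 0, 0), c(0, 1, 1)), 0)
  expect_error(sex_aware_maf(c(NA, NA), c(0, 1)), "missing")
  # invariant: MAF <= 0.5 and invariant under allele relabeling
  set.seed(7)
  for (i in 1:25) {
    sex <- rbinom(12, 1, 0.5)
    d <- rbinom(12, 2, runif(1, 0.05, 0.95))
    expect_lte(sex_aware_maf(d, sex), 0.5)
    expect_equal(sex_aware_maf(d, sex), sex_aware_maf(2 - d, sex))
  }
})

test_that("expression, annotation, peaks and catalog TSVs round-trip", {
  si <- sample_info(c("a", "b", "c"), c(0L, 1L, 1L))
  m <- matrix(rnorm(9), 3, dimnames = list(paste0("g", 1:3), si$sample_id))
  expr <- expression_matrix(m, si)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expr, path)
  expr2 <- read_expression(path, si)
  expect_equal(expr2$values, expr$values, tolerance = 1e-12)

  # minus-strand annotation given in transcript orientation is normalized
  ann <- gene_annotation(c("g1", "g2"), c("chr1", "chrX"),
                         tss = c(100L, 900L), tes = c(500L, 400L),
                         strand = c("+", "-"))
  expect_true(all(ann$tss <= ann$tes))
  expect_equal(gene_start_site(ann), c(100L, 900L))
  apath <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ann, apath)
  expect_equal(as.data.frame(read_annotation(apath)), as.data.frame(ann))

  # BED half-open convention: "chrX 100 200" spans 100 bp
  counts <- matrix(c(5L, 0L, 3L, 2L, 7L, 1L), 2,
                   dimnames = list(c("p1", "p2"), si$sample_id))
  pk <- peak_count_matrix(counts, c("chrX", "chr1"), c(100L, 0L),
                          c(200L, 50L), si)
  expect_equal(pk$end[1] - pk$start[1], 100L)
  bed <- withr::local_tempfile(fileext = ".bed")
  cts <- withr::local_tempfile(fileext = ".tsv")
  write_peaks(pk, bed, cts)
  pk2 <- read_peaks(bed, cts, si)
  expect_equal(pk2$counts, pk$counts)
  expect_error(peak_count_matrix(counts, c("chr1", "chr1"), c(10L, 5L),
                                 c(10L, 50L), si), "start < end")

  cat_ <- gwas_catalog(c("T1", "T1"), c("rs1", "rs2"), c(1e-9, 1e-10),
                       c("chr1", "chr1"), c(100L, 200L))
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_gwas_catalog(cat_, cpath)
  expect_equal(as.data.frame(read_gwas_catalog(cpath)), as.data.frame(cat_))
  expect_error(gwas_catalog("T", "rs", 0, "chr1", 1L), "gwas_p")
})

test_that("typed constructors enforce their invariants", {
  expect_error(sample_info(c("a", "a"), c(0L, 1L)), "unique")
  expect_error(sample_info("a", 2L), "sex")
  si <- sample_info(c("a", "b"), c(0L, 1L))
  expect_error(genotype_matrix(rbind(v1 = c(3, 0)), "chr1", 1L, si), "0/1/2")
  expect_error(genotype_matrix(rbind(v1 = c(1, 1)), "chrX", 1L, si),
               "x_coding")
  expect_error(expression_matrix(rbind(g1 = c(0.5, 1)), si, kind = "counts"),
               "integers")
  df <- data.frame(individual = "i", gene_id = "g", site = "s",
                   ref_count = 1L, alt_count = 2L, h = 2L, sex = 0L)
  expect_error(ase_table(df), "h must")
})
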