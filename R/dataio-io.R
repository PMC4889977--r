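# Readers/writers for the plain-text exchange formats: GT-only VCF 4.x,
# TSV with header for expression/annotation/catalog/ASE, BED3+ for peaks.

gt_to_allele_counts <- function(gt) {
  # returns list(alt = #alt alleles, n = #alleles) per GT string; NA for missing
  gt <- sub(":.*", "", gt)
  alleles <- strsplit(gt, "[/|]")
  alt <- vapply(alleles, function(a) {
    if (any(a == "." | is.na(a))) return(NA_integer_)
    sum(a != "0")
  }, integer(1))
  n <- lengths(alleles)
  list(alt = alt, n = n)
}

#' Read a GT-only VCF into a genotype matrix
#'
#' Autosomal genotypes become alternate-allele dosages. On chrX, male calls
#' with a single allele (or homozygous diploid calls) are mapped through
#' `x_coding`; heterozygous male chrX calls are impossible under hemizygosity,
#' set to missing, and counted in `n_male_het_x`.
#'
#' @param path VCF file (plain text or gzipped).
#' @param samples a [sample_info] table; every VCF sample must be listed.
#' @inheritParams genotype_matrix
#' @return A [genotype_matrix].
#' @export
read_vcf <- function(path, samples, x_coding = c("full_dosage", "haploid"),
                     x_chrom = "chrX") {
  x_coding <- match.arg(x_coding)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  vcf_samples <- colnames(gt)
  unknown <- setdiff(vcf_samples, samples$sample_id)
  if (length(unknown))
    stop("VCF samples without sex information: ", paste(unknown, collapse = ", "))
  samples <- samples[match(vcf_samples, samples$sample_id), , drop = FALSE]
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ids <- as.character(fix[, "ID"])
  ids[is.na(ids) | ids == "."] <- paste0(chrom, ":", pos)[is.na(ids) | ids == "."]

  ac <- gt_to_allele_counts(as.vector(gt))
  alt <- matrix(ac$alt, nrow = nrow(gt))
  nal <- matrix(ac$n, nrow = nrow(gt))
  bad <- !is.na(alt) & !(nal %in% c(1L, 2L))
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed GT at variant record %d (%s), sample %s",
                 i[1], ids[i[1]], vcf_samples[i[2]]))
  }
  dos <- alt
  # diploid calls count alleles directly; haploid calls handled below
  xi <- chrom %in% c(x_chrom, "X", "chrX")
  male <- samples$sex == 0L
  n_male_het <- 0L
  if (any(xi) && any(male)) {
    mx <- which(xi)
    for (j in which(male)) {
      a <- alt[mx, j]; k <- nal[mx, j]
      het <- !is.na(a) & k == 2L & a == 1L
      n_male_het <- n_male_het + sum(het)
      a[het] <- NA_integer_
      # haploid call or homozygous diploid -> one effective allele
      allele <- ifelse(k == 1L, a, a / 2L)
      dos[mx, j] <- if (x_coding == "full_dosage") 2 * allele else allele
    }
  }
  # haploid calls outside chrX males are rejected
  hap_bad <- nal == 1L & !(matrix(xi, nrow(gt), ncol(gt)) &
                             matrix(male, nrow(gt), ncol(gt), byrow = TRUE))
  if (any(hap_bad & !is.na(alt))) {
    i <- which(hap_bad & !is.na(alt), arr.ind = TRUE)[1, ]
    stop(sprintf("haploid GT outside male chrX at record %d, sample %s",
                 i[1], vcf_samples[i[2]]))
  }
  rownames(dos) <- ids
  if (n_male_het > 0)
    warning(n_male_het, " heterozygous male chrX calls set to missing")
  g <- genotype_matrix(dos, chrom, pos, samples, x_coding, x_chrom)
  g$n_male_het_x <- n_male_het
  g
}

#' Write a genotype matrix as a GT-only VCF
#'
#' @param g a [genotype_matrix].
#' @param path output path (plain text).
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples$sample_id), collapse = "\t")),
             con)
  xi <- is_x(g)
  male <- g$samples$sex == 0L
  dip <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(g$dosage))) {
    d <- g$dosage[i, ]
    gt <- character(length(d))
    if (xi[i]) {
      allele <- ifelse(male, if (g$x_coding == "full_dosage") d / 2 else d, NA)
      gt[male] <- ifelse(is.na(allele[male]), ".", as.character(allele[male]))
      gt[!male] <- ifelse(is.na(d[!male]), "./.", dip[d[!male] + 1])
    } else {
      gt <- ifelse(is.na(d), "./.", dip[d + 1])
    }
    writeLines(paste(c(g$chrom[i], g$pos[i], rownames(g$dosage)[i], "A", "G",
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Sex-aware minor allele frequency
#'
#' On chrX each male contributes one allele and each female two; on autosomes
#' everyone contributes two. Always returns the minor (<= 0.5) frequency.
#'
#' @param dosage numeric dosage vector for one variant (NA = missing).
#' @param sex 0/1 vector aligned with `dosage`.
#' @param chrx logical: is the variant on chrX?
#' @param x_coding coding used for male chrX dosages.
#' @return Minor allele frequency in `[0, 0.5]`.
#' @export
sex_aware_maf <- function(dosage, sex, chrx = FALSE,
                          x_coding = c("full_dosage", "haploid")) {
  x_coding <- match.arg(x_coding)
  ok <- !is.na(dosage)
  if (!any(ok)) stop("all genotypes missing: allele frequency undefined")
  d <- dosage[ok]; s <- sex[ok]
  if (chrx) {
    male <- s == 0
    alt_m <- if (x_coding == "full_dosage") d[male] / 2 else d[male]
    alt <- sum(alt_m) + sum(d[!male])
    tot <- sum(male) + 2 * sum(!male)
  } else {
    alt <- sum(d)
    tot <- 2 * length(d)
  }
  f <- alt / tot
  min(f, 1 - f)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
}

write_tsv <- function(df, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    df <- cbind(stats::setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                                rownames_as), as.data.frame(df))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write an expression matrix TSV (genes in rows, first column gene_id)
#'
#' @param path TSV with header: `gene_id` then one column per sample.
#' @param samples a [sample_info] table; columns are reordered to match it.
#' @param kind `"residuals"` or `"counts"`.
#' @return An [expression_matrix].
#' @export
read_expression <- function(path, samples, kind = c("residuals", "counts")) {
  kind <- match.arg(kind)
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  missing <- setdiff(samples$sample_id, colnames(m))
  if (length(missing)) stop("expression file lacks samples: ",
                            paste(missing, collapse = ", "))
  expression_matrix(m[, samples$sample_id, drop = FALSE], samples, kind)
}

#' @rdname read_expression
#' @param expr an [expression_matrix] to write.
#' @export
write_expression <- function(expr, path) {
  write_tsv(expr$values, path, rownames_as = "gene_id")
}

#' Read/write gene annotation TSV
#'
#' Columns `gene_id`, `chrom`, `tss`, `tes`, `strand`. Coordinates given in
#' transcript orientation are normalized so `tss <= tes` genomically.
#'
#' @param path TSV path.
#' @return A [gene_annotation].
#' @export
read_annotation <- function(path) {
  df <- read_tsv(path)
  gene_annotation(df$gene_id, df$chrom, df$tss, df$tes, df$strand)
}

#' @rdname read_annotation
#' @param ann a [gene_annotation] to write.
#' @export
write_annotation <- function(ann, path) write_tsv(as.data.frame(ann), path)

#' Read/write an ATAC peak set (BED3+ intervals plus counts TSV)
#'
#' @param bed_path BED file: chrom, start, end, peak_id (0-based half-open).
#' @param counts_path TSV: `peak_id` column then one column per sample.
#' @param samples a [sample_info] table.
#' @return A [peak_count_matrix].
#' @export
read_peaks <- function(bed_path, counts_path, samples) {
  bed <- utils::read.table(bed_path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(bed)[1:4] <- c("chrom", "start", "end", "peak_id")
  df <- read_tsv(counts_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!identical(sort(rownames(m)), sort(bed$peak_id)))
    stop("BED and counts peak ids disagree")
  m <- m[bed$peak_id, samples$sample_id, drop = FALSE]
  peak_count_matrix(m, bed$chrom, bed$start, bed$end, samples)
}

#' @rdname read_peaks
#' @param peaks a [peak_count_matrix] to write.
#' @export
write_peaks <- function(peaks, bed_path, counts_path) {
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end, rownames(peaks$counts))
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv(peaks$counts, counts_path, rownames_as = "peak_id")
  invisible(bed_path)
}

#' Read/write a GWAS catalog TSV
#'
#' Columns `trait`, `variant_id`, `gwas_p`, `chrom`, `pos`.
#' @param path TSV path.
#' @return A [gwas_catalog].
#' @export
read_gwas_catalog <- function(path) {
  df <- read_tsv(path)
  gwas_catalog(df$trait, df$variant_id, df$gwas_p, df$chrom, df$pos)
}

#' @rdname read_gwas_catalog
#' @param cat_ a [gwas_catalog] to write.
#' @export
write_gwas_catalog <- function(cat_, path) write_tsv(as.data.frame(cat_), path)

#' Read/write an allele-specific expression count TSV
#'
#' @param path TSV with the [ase_table] columns.
#' @return An [ase_table].
#' @export
read_ase <- function(path) ase_table(read_tsv(path))

#' @rdname read_ase
#' @param ase an [ase_table] to write.
#' @export
write_ase <- function(ase, path) write_tsv(as.data.frame(ase), path)
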