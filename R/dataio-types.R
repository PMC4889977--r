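#' @keywords internal
"_PACKAGE"

# Sex is coded 0 = male, 1 = female throughout the package, so that positive
# sex and genotype-by-sex coefficients mean "larger in females".

#' Sample metadata table
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param sex integer vector, 0 = male, 1 = female.
#' @return A `sample_info` data.frame with columns `sample_id`, `sex`.
#' @export
sample_info <- function(sample_id, sex) {
  sample_id <- as.character(sample_id)
  sex <- as.integer(sex)
  if (anyDuplicated(sample_id)) stop("sample_ids must be unique")
  if (length(sex) != length(sample_id)) stop("sample_id and sex lengths differ")
  if (!all(sex %in% c(0L, 1L))) stop("sex must be coded 0 (male) / 1 (female)")
  structure(data.frame(sample_id = sample_id, sex = sex,
                       stringsAsFactors = FALSE),
            class = c("sample_info", "data.frame"))
}

#' Genotype dosage matrix with X-aware coding
#'
#' Holds variant x sample dosages. Autosomal dosages count alternate alleles
#' (0/1/2). On chrX, males are hemizygous: under `x_coding = "full_dosage"` a
#' male alternate allele is coded 2 (one X allele carries the same regression
#' dosage as a female homozygote), under `"haploid"` it is coded 1.
#' Missing genotypes are `NA`.
#'
#' @param dosage numeric matrix, variants in rows, samples in columns.
#' @param chrom character vector, chromosome per variant.
#' @param pos integer vector, 1-based position per variant.
#' @param samples a [sample_info] table matching the columns.
#' @param x_coding `"full_dosage"` or `"haploid"`.
#' @param x_chrom chromosome name treated as X (default `"chrX"`; `"X"` is
#'   also recognized).
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosage, chrom, pos, samples,
                            x_coding = c("full_dosage", "haploid"),
                            x_chrom = "chrX") {
  x_coding <- match.arg(x_coding)
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) stop("dosage must have variant_id rownames")
  if (anyDuplicated(rownames(dosage))) stop("variant_ids must be unique")
  stopifnot(nrow(dosage) == length(chrom), nrow(dosage) == length(pos),
            ncol(dosage) == nrow(samples))
  if (any(pos <= 0)) stop("positions must be strictly positive")
  colnames(dosage) <- samples$sample_id
  obj <- structure(list(dosage = dosage, chrom = as.character(chrom),
                        pos = as.integer(pos), samples = samples,
                        x_coding = x_coding, x_chrom = x_chrom,
                        n_male_het_x = 0L),
                   class = "genotype_matrix")
  validate_genotype_matrix(obj)
  obj
}

is_x <- function(g, chrom = g$chrom) chrom %in% c(g$x_chrom, "X", "chrX")

validate_genotype_matrix <- function(g) {
  d <- g$dosage
  xi <- is_x(g)
  male <- g$samples$sex == 0L
  auto <- d[!xi, , drop = FALSE]
  if (!all(auto %in% c(0, 1, 2, NA))) stop("autosomal dosages must be 0/1/2/NA")
  dx <- d[xi, , drop = FALSE]
  dm <- dx[, male, drop = FALSE]
  ok_m <- if (g$x_coding == "full_dosage") c(0, 2, NA) else c(0, 1, NA)
  if (!all(dm %in% ok_m)) stop("male chrX dosages violate x_coding ", g$x_coding)
  if (!all(dx[, !male, drop = FALSE] %in% c(0, 1, 2, NA)))
    stop("female chrX dosages must be 0/1/2/NA")
  invisible(g)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants x %d samples (%d chrX), x_coding=%s\n",
              nrow(x$dosage), ncol(x$dosage), sum(is_x(x)), x$x_coding))
  invisible(x)
}

#' Gene annotation table
#'
#' TSS/TES are stored in genomic orientation (`tss <= tes`); the strand
#' records the transcribed direction, so the biological start of a minus
#' strand gene is `tes`.
#'
#' @param gene_id,chrom character vectors.
#' @param tss,tes 1-based integer coordinates; may be given in transcript
#'   orientation (`tss > tes` on minus strand) and are normalized.
#' @param strand `"+"` or `"-"`.
#' @return A `gene_annotation` data.frame.
#' @export
gene_annotation <- function(gene_id, chrom, tss, tes, strand) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("gene_ids must be unique")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  lo <- pmin(tss, tes); hi <- pmax(tss, tes)
  structure(data.frame(gene_id = gene_id, chrom = as.character(chrom),
                       tss = as.integer(lo), tes = as.integer(hi),
                       strand = as.character(strand), stringsAsFactors = FALSE),
            class = c("gene_annotation", "data.frame"))
}

# strand-aware transcription start in genomic coordinates
gene_start_site <- function(ann) ifelse(ann$strand == "+", ann$tss, ann$tes)

#' Expression matrix (counts or residuals)
#'
#' @param values gene x sample numeric matrix with gene_id rownames and
#'   sample_id colnames.
#' @param samples a [sample_info] table matching the columns.
#' @param kind `"counts"` (non-negative integers) or `"residuals"` (finite
#'   covariate-corrected values).
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, samples, kind = c("residuals", "counts")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene_id rownames")
  if (anyDuplicated(rownames(values))) stop("gene_ids must be unique")
  if (ncol(values) != nrow(samples)) stop("sample dimension mismatch")
  if (kind == "counts") {
    if (any(values < 0) || any(values != round(values)))
      stop("counts must be non-negative integers")
  } else if (!all(is.finite(values))) stop("residual values must be finite")
  colnames(values) <- samples$sample_id
  structure(list(values = values, samples = samples, kind = kind),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (%s): %d genes x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' ATAC peak count matrix with BED intervals
#'
#' Intervals follow the BED convention: 0-based, half-open `[start, end)`.
#'
#' @param counts peak x sample non-negative integer matrix, peak_id rownames.
#' @param chrom,start,end per-peak interval (0-based half-open).
#' @param samples a [sample_info] table.
#' @return A `peak_count_matrix` object.
#' @export
peak_count_matrix <- function(counts, chrom, start, end, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have peak_id rownames")
  if (anyDuplicated(rownames(counts))) stop("peak ids must be unique")
  stopifnot(nrow(counts) == length(chrom), length(chrom) == length(start),
            length(start) == length(end), ncol(counts) == nrow(samples))
  if (any(start >= end)) stop("BED intervals require start < end")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, chrom = as.character(chrom),
                 start = as.integer(start), end = as.integer(end),
                 samples = samples),
            class = "peak_count_matrix")
}

#' GWAS catalog table
#'
#' @param trait,variant_id character; `gwas_p` in (0, 1]; `chrom`, `pos`
#'   variant location.
#' @return A `gwas_catalog` data.frame.
#' @export
gwas_catalog <- function(trait, variant_id, gwas_p, chrom, pos) {
  if (length(gwas_p) && (any(gwas_p <= 0) || any(gwas_p > 1)))
    stop("gwas_p must lie in (0, 1]")
  structure(data.frame(trait = as.character(trait),
                       variant_id = as.character(variant_id),
                       gwas_p = as.numeric(gwas_p),
                       chrom = as.character(chrom), pos = as.integer(pos),
                       stringsAsFactors = FALSE),
            class = c("gwas_catalog", "data.frame"))
}

#' Allele-specific expression count table
#'
#' One row per (individual, gene, site). `h` is the phased regulatory-variant
#' dosage contrast: +1 when the individual's alternate regulatory allele is on
#' the haplotype carrying the counted alternate transcribed allele, -1 when on
#' the opposite haplotype, 0 for regulatory homozygotes (baseline only).
#'
#' @param df data.frame with columns `individual`, `gene_id`, `site`,
#'   `ref_count`, `alt_count`, `h`, `sex`.
#' @return An `ase_table` data.frame.
#' @export
ase_table <- function(df) {
  need <- c("individual", "gene_id", "site", "ref_count", "alt_count", "h", "sex")
  if (!all(need %in% names(df))) stop("missing ASE columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$ref_count < 0) || any(df$alt_count < 0) ||
      any(df$ref_count != round(df$ref_count)) || any(df$alt_count != round(df$alt_count)))
    stop("ASE counts must be non-negative integers")
  if (!all(df$h %in% c(-1, 0, 1))) stop("h must be -1, 0 or +1")
  if (!all(df$sex %in% c(0, 1))) stop("sex must be 0/1")
  structure(as.data.frame(df), class = c("ase_table", "data.frame"))
}
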