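# Negative-binomial differential chromatin accessibility between the sexes
# and its directional integration with expression / interaction eQTLs.
#
# The two-group test conditions on the total count of a peak: under the
# null, the group sums are independent NB variables with moments determined
# by the common rate, the size factors and the dispersion; the p-value sums
# the joint probabilities of all splits of the total that are no more likely
# than the observed split (computed in log space).

#' Median-of-ratios size factors
#'
#' Per-sample median of count ratios to the per-peak geometric-mean
#' reference (peaks with any zero are excluded from the reference). When no
#' peak is all-positive, falls back to total-count (library size) factors
#' normalized to geometric mean 1, with a warning.
#'
#' @param counts peak x sample integer matrix.
#' @return Numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no peak with all-positive counts; using library-size factors")
    ls <- colSums(counts)
    return(ls / exp(mean(log(ls))))
  }
  # exp of the median log-ratio (even-count medians average on the log scale)
  lc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lc)
  exp(apply(lc - ref, 2, stats::median))
}

#' Per-peak negative-binomial dispersion
#'
#' Method-of-moments on size-factor-normalized counts: within-group sample
#' variances are pooled (df-weighted), the sampling (Poisson) part
#' `m * mean(1/sf)` is subtracted, and `alpha = max(0, (v - z)/m^2)`.
#' With `sharing = "trend"` a mean-dispersion trend `a0/m + a1` is fitted
#' across peaks and used as the per-peak value; `"max"` takes the larger of
#' the raw and trend values (conservative); `"raw"` uses per-peak estimates.
#'
#' @param counts peak x sample matrix.
#' @param groups group label per sample (e.g. sex).
#' @param sf size factors (default computed).
#' @param sharing `"trend"`, `"max"` or `"raw"`.
#' @return data.frame per peak: `mean` (normalized), `alpha_raw`, `alpha`.
#'   Zero-mean peaks get NA.
#' @export
estimate_dispersion <- function(counts, groups, sf = size_factors(counts),
                                sharing = c("trend", "max", "raw")) {
  sharing <- match.arg(sharing)
  counts <- as.matrix(counts)
  q <- sweep(counts, 2, sf, "/")
  m <- rowMeans(q)
  glev <- unique(groups)
  v <- 0; df <- 0; zc <- 0
  for (g in glev) {
    j <- groups == g
    if (sum(j) < 2) stop("need >= 2 samples per group")
    v <- v + apply(q[, j, drop = FALSE], 1, stats::var) * (sum(j) - 1)
    df <- df + sum(j) - 1
    zc <- zc + mean(1 / sf[j]) * (sum(j) - 1)
  }
  v <- v / df
  z <- m * (zc / df)
  alpha_raw <- ifelse(m > 0, pmax(0, (v - z) / m^2), NA_real_)
  alpha <- alpha_raw
  if (sharing != "raw" && sum(!is.na(alpha_raw) & m > 0) >= 10) {
    use <- !is.na(alpha_raw) & m > 0
    fit <- stats::lm(alpha_raw[use] ~ I(1 / m[use]))
    trend <- pmax(0, stats::coef(fit)[1] + stats::coef(fit)[2] / m)
    alpha <- if (sharing == "trend") trend else pmax(alpha_raw, trend)
    alpha[!use] <- NA_real_
  }
  data.frame(mean = m, alpha_raw = alpha_raw, alpha = alpha)
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

nb_split_logprob <- function(a, ks, mu_a, mu_b, var_a, var_b) {
  dnb <- function(x, mu, v) {
    if (v > mu * (1 + 1e-8)) {
      size <- mu^2 / (v - mu)
      stats::dnbinom(x, mu = mu, size = size, log = TRUE)
    } else stats::dpois(x, mu, log = TRUE)
  }
  dnb(a, mu_a, var_a) + dnb(ks - a, mu_b, var_b)
}

#' Conditional NB exact test for one peak
#'
#' @param k integer counts for the peak across samples.
#' @param groups two-level label per sample (second level is the "female" /
#'   numerator group for the fold; with 0/1 sex, 1 = female).
#' @param sf size factors.
#' @param alpha NB dispersion for the peak.
#' @return list: `p`, `log2_fold` (group2 / group1 normalized means),
#'   `mean1`, `mean2`.
#' @export
nb_test <- function(k, groups, sf, alpha) {
  glev <- sort(unique(groups))
  stopifnot(length(glev) == 2)
  j1 <- groups == glev[1]; j2 <- groups == glev[2]
  if (sum(j1) < 2 || sum(j2) < 2) stop("need >= 2 samples per group")
  ka <- sum(k[j1]); kb <- sum(k[j2]); ks <- ka + kb
  s1 <- sf[j1]; s2 <- sf[j2]
  m1 <- mean(k[j1] / s1); m2 <- mean(k[j2] / s2)
  lfc <- log2((m2 + 0.5 / mean(s2)) / (m1 + 0.5 / mean(s1)))
  if (ks == 0) return(list(p = 1, log2_fold = 0, mean1 = 0, mean2 = 0))
  qhat <- ks / sum(sf)
  mu_a <- qhat * sum(s1); mu_b <- qhat * sum(s2)
  var_a <- sum(s1 * qhat + alpha * (s1 * qhat)^2)
  var_b <- sum(s2 * qhat + alpha * (s2 * qhat)^2)
  lp <- nb_split_logprob(0:ks, ks, mu_a, mu_b, var_a, var_b)
  lobs <- lp[ka + 1]
  denom <- logsumexp(lp)
  keep <- lp <= lobs + log(REL_TOL)
  p <- exp(logsumexp(lp[keep]) - denom)
  list(p = min(1, p), log2_fold = lfc, mean1 = m1, mean2 = m2)
}

#' Matrix driver for the NB exact test
#'
#' @param counts feature x sample matrix.
#' @param sex 0/1 (male/female) label per sample.
#' @param sf size factors (default computed).
#' @param sharing dispersion sharing mode (see [estimate_dispersion]).
#' @return data.frame per feature: mean_m, mean_f, alpha, log2_fold (F/M),
#'   p, q, direction. Zero-count features get p = 1.
#' @export
nb_diff_test <- function(counts, sex, sf = size_factors(counts),
                         sharing = "trend") {
  counts <- as.matrix(counts)
  disp <- estimate_dispersion(counts, sex, sf, sharing)
  res <- lapply(seq_len(nrow(counts)), function(i) {
    if (is.na(disp$alpha[i]) || disp$mean[i] == 0)
      return(data.frame(mean_m = 0, mean_f = 0, alpha = NA_real_,
                        log2_fold = 0, p = 1))
    r <- nb_test(counts[i, ], sex, sf, disp$alpha[i])
    data.frame(mean_m = r$mean1, mean_f = r$mean2, alpha = disp$alpha[i],
               log2_fold = r$log2_fold, p = r$p)
  })
  out <- do.call(rbind, res)
  rownames(out) <- rownames(counts)
  out$q <- bh_fdr(out$p)
  out$direction <- ifelse(out$log2_fold >= 0, "female", "male")
  out
}

#' Differential accessibility between the sexes
#'
#' @param peaks a [peak_count_matrix].
#' @param fdr FDR threshold used for the `significant` flag (default 0.10).
#' @param sharing dispersion sharing mode.
#' @return data.frame per peak (as [nb_diff_test]) plus interval columns and
#'   a `significant` flag.
#' @export
atac_sex_test <- function(peaks, fdr = 0.10, sharing = "trend") {
  res <- nb_diff_test(peaks$counts, peaks$samples$sex, sharing = sharing)
  res$chrom <- peaks$chrom; res$start <- peaks$start; res$end <- peaks$end
  res$peak_id <- rownames(peaks$counts)
  res$significant <- res$q < fdr
  res
}

#' Link peaks to genes through a strand-oriented upstream window
#'
#' A peak is linked to a gene when its interval intersects the window from
#' `upstream_bp` before the strand-aware TSS to the TSS itself (minus-strand
#' genes look at higher coordinates). With `strand_oriented = FALSE` the
#' window is always taken on the lower-coordinate side.
#'
#' @param peaks a [peak_count_matrix].
#' @param annotation a [gene_annotation].
#' @param upstream_bp window size in bp (default 40000).
#' @param strand_oriented orient the window by gene strand (default TRUE).
#' @return data.frame with columns `peak_id`, `gene_id` (multi-links kept).
#' @export
peak_gene_link <- function(peaks, annotation, upstream_bp = 40000,
                           strand_oriented = TRUE) {
  tss <- if (strand_oriented) gene_start_site(annotation) else annotation$tss
  up <- if (strand_oriented) annotation$strand == "+" else rep(TRUE, nrow(annotation))
  win_lo <- ifelse(up, tss - upstream_bp, tss)
  win_hi <- ifelse(up, tss, tss + upstream_bp)
  out <- list()
  for (ch in unique(annotation$chrom)) {
    gi <- which(annotation$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (!length(gi) || !length(pi)) next
    # peaks are 0-based half-open: convert to 1-based closed
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(peaks$start[pi] + 1L, peaks$end[pi]),
      IRanges::IRanges(win_lo[gi], win_hi[gi]))
    if (!length(hits)) next
    out[[ch]] <- data.frame(
      peak_id = rownames(peaks$counts)[pi][S4Vectors::queryHits(hits)],
      gene_id = annotation$gene_id[gi][S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(peak_id = character(0),
                                      gene_id = character(0))
  rownames(out) <- NULL
  out
}

#' Enrichment of sex-specific genes near sex-specific peaks
#'
#' Per q-value threshold on the peak test, Fisher's exact test of (gene is
#' linked to a sex-specific upstream peak) x (gene flag, e.g. sex-specific
#' expression or interaction eQTL). The directional test asks, among genes
#' with both signals, whether the peak-open sex and the expression-up sex
#' oppose each other more often than expected (one-sided).
#'
#' @param peak_res output of [atac_sex_test].
#' @param gene_flags named logical vector (gene universe with flags).
#' @param gene_dir optional named direction per gene (`"female"`/`"male"`)
#'   for the directional test.
#' @param link output of [peak_gene_link].
#' @param thresholds q thresholds to scan.
#' @return list: `enrichment` data.frame (per threshold: OR, CI, p),
#'   `directional` a `sexqtl_test` or NULL.
#' @export
integration_enrichment <- function(peak_res, gene_flags, link,
                                   gene_dir = NULL,
                                   thresholds = c(0.05, 0.1, 0.2)) {
  if (!nrow(link)) stop("empty peak-gene link map")
  genes <- names(gene_flags)
  enr <- lapply(thresholds, function(thr) {
    sig_peaks <- peak_res$peak_id[peak_res$q < thr]
    linked <- genes %in% link$gene_id[link$peak_id %in% sig_peaks]
    tab <- rbind(c(sum(linked & gene_flags), sum(linked & !gene_flags)),
                 c(sum(!linked & gene_flags), sum(!linked & !gene_flags)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      return(data.frame(threshold = thr, or = NA_real_, lo = NA_real_,
                        hi = NA_real_, p = NA_real_))
    tr <- fisher_exact(tab, or_ci = TRUE)
    data.frame(threshold = thr, or = tr$estimate, lo = tr$conf_int[1],
               hi = tr$conf_int[2], p = tr$p_value)
  })
  directional <- NULL
  if (!is.null(gene_dir)) {
    sig_peaks <- peak_res[peak_res$significant, c("peak_id", "direction")]
    lk <- merge(link, sig_peaks, by = "peak_id")
    lk$gdir <- gene_dir[lk$gene_id]
    lk <- lk[!is.na(lk$gdir) & gene_flags[lk$gene_id], , drop = FALSE]
    if (nrow(lk)) {
      oppose <- lk$direction != lk$gdir
      peak_f <- lk$direction == "female"
      tab <- rbind(c(sum(peak_f & oppose), sum(peak_f & !oppose)),
                   c(sum(!peak_f & oppose), sum(!peak_f & !oppose)))
      # one-sided: discordance between peak-open sex and expression-up sex
      k <- sum(oppose)
      directional <- binomial_exact(k, nrow(lk), sided = "greater")
      attr(directional, "n_oppose") <- k
      attr(directional, "n_linked") <- nrow(lk)
    }
  }
  list(enrichment = do.call(rbind, enr), directional = directional)
}

#' X-inactivation-escape enrichment in top sex-specific X peaks
#'
#' Ranks chrX peaks by nominal p (ties by |log2 fold|, descending), takes the
#' top decile (floor), and tests with Fisher's exact test whether genes
#' linked to top peaks are enriched for escape genes relative to genes
#' linked to the remaining (sex-shared) X peaks.
#'
#' @param peak_res output of [atac_sex_test].
#' @param escape_genes character vector of escape gene ids.
#' @param link output of [peak_gene_link].
#' @param top_fraction fraction of X peaks called "top" (default 0.1).
#' @param x_chrom chromosome names treated as X.
#' @return A `sexqtl_test` with proportions attached as attributes.
#' @export
escape_enrichment <- function(peak_res, escape_genes, link,
                              top_fraction = 0.1, x_chrom = c("chrX", "X")) {
  if (!length(escape_genes)) stop("empty escape gene list")
  px <- peak_res[peak_res$chrom %in% x_chrom, , drop = FALSE]
  if (!nrow(px)) stop("no X peaks")
  ord <- order(px$p, -abs(px$log2_fold), px$peak_id)
  n_top <- floor(nrow(px) * top_fraction)
  top_ids <- px$peak_id[ord[seq_len(n_top)]]
  lk <- link[link$peak_id %in% px$peak_id, , drop = FALSE]
  genes <- unique(lk$gene_id)
  in_top <- genes %in% lk$gene_id[lk$peak_id %in% top_ids]
  esc <- genes %in% escape_genes
  tab <- rbind(c(sum(in_top & esc), sum(in_top & !esc)),
               c(sum(!in_top & esc), sum(!in_top & !esc)))
  tr <- fisher_exact(tab, sided = "greater", or_ci = TRUE)
  attr(tr, "prop_top") <- if (any(in_top)) mean(esc[in_top]) else NA_real_
  attr(tr, "prop_shared") <- if (any(!in_top)) mean(esc[!in_top]) else NA_real_
  tr
}
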