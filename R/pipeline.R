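# End-to-end orchestration: simulate (or load) a cohort, run every analysis
# stage, and write plain-text outputs plus a reproducibility manifest.
# A single global seed fans out to per-stage seeds by fixed offsets
# (simulate: seed+1..seed+5 inside simulate_cohort; subsample draws:
# seed+10; GWAS stage: seed+11), so stages are independently reproducible.

stage_write <- function(df, dir, name) {
  write_tsv(df, file.path(dir, paste0(name, ".tsv")))
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes simulate -> DE/DV -> eQTL -> interaction -> PVE -> ASE -> ATAC ->
#' GWAS sex-bias, writing one TSV per stage plus the simulated inputs and a
#' `manifest.json` capturing the configuration, seeds and input digests.
#' Re-running with the same seed and configuration reproduces a
#' byte-identical output tree.
#'
#' @param out_dir output directory (created; must be empty or absent).
#' @param cfg a [sim_config]; its `seed` is overridden by `seed`.
#' @param seed global integer seed.
#' @param fdr_dv,fdr_de,fdr_atac significance thresholds per stage.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_all <- function(out_dir, cfg = sim_config(), seed = cfg$seed,
                    fdr_dv = 0.05, fdr_de = 0.05, fdr_atac = 0.10) {
  if (dir.exists(out_dir) && length(list.files(out_dir)))
    stop("output directory exists and is not empty: ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg$seed <- seed
  co <- simulate_cohort(cfg)

  # --- write simulated inputs -------------------------------------------
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir)
  write_vcf(co$genotypes, file.path(in_dir, "genotypes.vcf"))
  write_expression(co$expr, file.path(in_dir, "expression_residuals.tsv"))
  write_expression(co$counts, file.path(in_dir, "expression_counts.tsv"))
  write_annotation(co$annotation, file.path(in_dir, "annotation.tsv"))
  write_peaks(co$peaks, file.path(in_dir, "peaks.bed"),
              file.path(in_dir, "peak_counts.tsv"))
  write_gwas_catalog(co$catalog, file.path(in_dir, "gwas_catalog.tsv"))
  write_ase(co$ase, file.path(in_dir, "ase.tsv"))
  write_tsv(co$samples, file.path(in_dir, "samples.tsv"))
  jsonlite::write_json(co$truth, file.path(in_dir, "truth.json"),
                       dataframe = "columns", na = "null", digits = NA)

  sex <- co$samples$sex
  sub_seed <- seed + 10L

  # --- differential mean / variance -------------------------------------
  idx <- match_subsample(sex, sub_seed)
  expr_m <- expression_matrix(co$expr$values[, idx, drop = FALSE],
                              sample_info(co$samples$sample_id[idx], sex[idx]),
                              "residuals")
  dv <- test_dv(expr_m, strategy = "B_gated")
  de <- test_de(expr_m, method = "welch")
  stage_write(dv, out_dir, "dv")
  stage_write(de, out_dir, "de")

  # --- eQTL + interaction mapping ----------------------------------------
  eq <- map_cis_eqtl(co$genotypes, co$expr, co$annotation, "additive")
  ix <- map_cis_eqtl(co$genotypes, co$expr, co$annotation, "interaction")
  stage_write(eq$summary, out_dir, "eqtl_gene_summary")
  stage_write(ix$summary, out_dir, "interaction_gene_summary")
  stage_write(ix$records, out_dir, "interaction_records")

  # --- per-sex PVE -------------------------------------------------------
  pve <- pve_by_sex(co$genotypes, co$expr, co$annotation, seed = sub_seed)
  stage_write(pve, out_dir, "pve")

  # --- ASE ---------------------------------------------------------------
  ase <- ase_scan(co$ase)
  if (!is.null(ase)) stage_write(ase, out_dir, "ase_fits")

  # --- ATAC --------------------------------------------------------------
  atac <- atac_sex_test(co$peaks, fdr = fdr_atac)
  stage_write(atac, out_dir, "atac")
  link <- peak_gene_link(co$peaks, co$annotation)
  stage_write(link, out_dir, "peak_gene_links")

  # --- GWAS sex bias -----------------------------------------------------
  gw <- gwas_sexbias(co$catalog, co$genotypes, co$expr, co$annotation,
                     seed = seed + 11L)
  if (!is.null(gw$traits)) stage_write(gw$traits, out_dir, "gwas_traits")
  if (!is.null(gw$variants)) stage_write(gw$variants, out_dir, "gwas_variants")

  # --- manifest ----------------------------------------------------------
  inputs <- list.files(in_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("sexqtl")),
    seed = seed,
    stage_seeds = list(simulate = seed + 1:5, subsample = sub_seed,
                       gwas = seed + 11L),
    thresholds = list(fdr_dv = fdr_dv, fdr_de = fdr_de, fdr_atac = fdr_atac),
    config = cfg[!vapply(cfg, is.list, logical(1))],
    filter_counts = list(eqtl = as.list(eq$filter_counts),
                         interaction = as.list(ix$filter_counts)),
    input_digests = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                            basename(inputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = co, dv = dv, de = de, eqtl = eq, interaction = ix,
                 pve = pve, ase = ase, atac = atac, link = link, gwas = gw))
}
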