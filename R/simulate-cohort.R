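#' Simulate a complete synthetic study
#'
#' Runs every generator in a fixed order and returns all layers of one
#' synthetic cohort: genotypes with the planted perfect-LD tag/indel pair,
#' gene annotation, the regulator's activity omics with true labels,
#' expression with the regulator-conditional eQTL, the paired knockdown
#' experiment, the motif flank + PWM, TAD/peak interval sets, and a
#' clinical table. Each generator draws from its own seed stream derived
#' from `cfg$seed`, so the whole object is bit-reproducible.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_cohort` list: cfg, geno, truth, genes, omics, labels,
#'   expression, knockdown, motif, tads, peaks, clinical.
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  gt <- simulate_genotypes(cfg)
  genes <- simulate_genes(cfg, gt$truth, gt$geno)
  ao <- simulate_activity_omics(cfg)
  expr <- simulate_expression(gt$geno, ao$labels, gt$truth, cfg)
  kd <- simulate_knockdown(gt$truth, cfg)
  motif <- simulate_sequence_and_pwm(gt$truth, cfg, gt$geno)
  iv <- simulate_intervals(gt$truth, cfg, gt$geno, genes)
  clinical <- simulate_clinical(gt$geno, gt$truth, cfg)
  structure(list(cfg = cfg, geno = gt$geno, truth = gt$truth,
                 genes = genes, omics = ao$cohort, labels = ao$labels,
                 expression = expr, knockdown = kd, motif = motif,
                 tads = iv$tads, peaks = iv$peaks, clinical = clinical),
            class = "sim_cohort")
}

#' Write a simulated study to standard-format fixture files
#'
#' Materializes every layer of a [simulate_cohort()] result as the plain
#' text formats the pipeline consumes: VCF genotypes, TSV matrices, BED
#' intervals, FASTA flank, PFM motif counts, JSON truth/placement records,
#' and a YAML pipeline config pointing at all of them with the default
#' thresholds.
#'
#' @param sim A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named list of the file paths written (invisibly), including
#'   `config` (the YAML usable with [run_pipeline()]).
#' @export
write_sim_fixtures <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  paths <- list(
    vcf = p("genotypes.vcf"),
    expression = p("expression.tsv"),
    genes = p("genes.tsv"),
    omics_expression = p("omics_expression.tsv"),
    cnv = p("cnv.tsv"),
    methylation = p("methylation.tsv"),
    promoter_cpgs = p("promoter_cpgs.txt"),
    knockdown = p("knockdown_expression.tsv"),
    knockdown_samples = p("knockdown_samples.tsv"),
    tads = p("tads.bed"),
    peaks = p("peaks.bed"),
    flank = p("flank.fasta"),
    pfm = p("motif.pfm"),
    motif_placement = p("motif_placement.json"),
    truth = p("truth.json"),
    clinical = p("clinical.tsv"),
    config = p("config.yaml")
  )
  write_vcf(sim$geno, paths$vcf)
  write_matrix_tsv(sim$expression, paths$expression)
  utils::write.table(sim$genes, paths$genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_matrix_tsv(sim$omics$expression, paths$omics_expression)
  write_matrix_tsv(sim$omics$cnv, paths$cnv)
  write_matrix_tsv(sim$omics$methylation, paths$methylation)
  writeLines(sim$omics$promoter_cpgs, paths$promoter_cpgs)
  write_matrix_tsv(sim$knockdown$expression, paths$knockdown)
  utils::write.table(sim$knockdown$samples, paths$knockdown_samples,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(sim$tads, paths$tads)
  write_bed(sim$peaks, paths$peaks)
  write_fasta(sim$motif$flank, "ref_flank", paths$flank)
  write_pfm(sim$motif$pwm, paths$pfm, name = "regulator_motif")
  jsonlite::write_json(sim$motif$placement, paths$motif_placement,
                       auto_unbox = TRUE, digits = NA)
  write_truth_json(sim$truth, paths$truth)
  utils::write.table(sim$clinical, paths$clinical, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cfg_yaml <- list(
    inputs = lapply(paths[setdiff(names(paths), "config")], normalizePath,
                    mustWork = FALSE),
    regulator = sim$cfg$regulator_id,
    thresholds = default_thresholds(),
    seed = sim$cfg$seed
  )
  yaml::write_yaml(cfg_yaml, paths$config)
  invisible(paths)
}

#' Default analysis thresholds
#'
#' The package-wide defaults: copy-number segment mean > 0.5, promoter
#' methylation beta <= 0.4, cis window 1 Mb, raw-p output threshold 0.05,
#' per-group FDR < 0.01, knockdown combined difference > 1.0, LD r^2 > 0.8
#' within 250 kb, promoter window 2000 bp upstream / 500 bp downstream.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(cnv = 0.5, beta = 0.4, cis_window_bp = 1e6, p_out = 0.05,
       fdr = 0.01, de_diff = 1.0, r2 = 0.8, ld_window_bp = 250000,
       promoter_upstream_bp = 2000, promoter_downstream_bp = 500)
}
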