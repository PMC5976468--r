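#' Simulate gene expression with a regulator-conditional genotype effect
#'
#' The planted target gene follows
#' `y = mu_g + shift * 1[active] + beta_active * dosage * 1[active] +
#'  beta_inactive * dosage * 1[inactive] + N(0, noise_sd)`,
#' i.e. an additive allelic effect present only in regulator-active patients
#' plus a group mean shift (the regulator upregulates its target). All other
#' genes are pure noise around gene-specific baselines.
#'
#' @param geno `genotype_matrix` (patient order defines the columns).
#' @param labels named logical vector of true activity per patient.
#' @param truth `planted_truth` naming the tag SNP and target gene.
#' @param cfg A [sim_config()].
#' @param active_shift Mean expression shift of the target gene in active
#'   patients (expression units; default 0.5).
#' @return gene x patient numeric matrix with `cfg$n_genes` rows.
#' @export
simulate_expression <- function(geno, labels, truth, cfg, active_shift = 0.5) {
  validate_sim_config(cfg)
  if (!identical(names(labels), geno$patient_ids)) {
    stop("patient sets of genotypes and activity labels are misaligned")
  }
  .seed_for(cfg, 401)
  n <- length(labels)
  gene_ids <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  baseline <- stats::runif(cfg$n_genes, 4, 8)
  expr <- matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$noise_sd),
                 nrow = cfg$n_genes) + baseline
  dimnames(expr) <- list(gene_ids, geno$patient_ids)

  dose <- geno$dosages[truth$tag_snp_id, ]
  act <- as.numeric(labels)
  expr[truth$target_gene_id, ] <- expr[truth$target_gene_id, ] +
    active_shift * act +
    truth$beta_active * dose * act +
    truth$beta_inactive * dose * (1 - act)
  expr
}

#' Null p-value stream for type-I-error calibration
#'
#' Generates `cfg$n_null_pairs` mutually independent SNP-gene pairs with no
#' genotype effect (each SNP is paired with its own gene, so the pairs share
#' nothing) and returns the additive-model association p-value of each pair.
#' Under the Gaussian noise model these p-values are exactly Uniform(0, 1),
#' which is what the calibration checks assert.
#'
#' @param cfg A [sim_config()]; `n_null_pairs`, `n_patients`, `maf_range`
#'   and `noise_sd` are used.
#' @return numeric vector of `cfg$n_null_pairs` p-values.
#' @export
null_pvalues <- function(cfg) {
  validate_sim_config(cfg)
  .seed_for(cfg, 877)
  m <- cfg$n_null_pairs
  n <- cfg$n_patients
  p_out <- numeric(m)
  for (i in seq_len(m)) {
    maf <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
    g <- stats::rbinom(n, 2L, maf)
    while (stats::var(g) == 0) g <- stats::rbinom(n, 2L, maf)
    y <- stats::rnorm(n, 0, cfg$noise_sd)
    p_out[i] <- fit_additive(g, y)$p_value
  }
  p_out
}
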