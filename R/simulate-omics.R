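#' Simulate the regulator's multi-omic activity signature
#'
#' Generates the three data layers used to call regulator activity:
#' regulator expression (log2 scale), copy-number segment mean at the
#' regulator locus, and beta-values at 14 promoter CpGs. Each criterion is a
#' noisy readout of a shared latent activity score (the true label plus
#' N(0, 0.25) jitter), so the three criteria are correlated but not
#' identical: most truly active patients pass all three, while a minority of
#' patients pass only one or two — the partial-overlap structure seen in
#' real regulator-amplified cohorts.
#'
#' Readout model (active label a in {0, 1}, latent z = a + N(0, 0.25)):
#' * expression = 10 + 2.2 z + N(0, 0.35)  (active mean 12.2, inactive 10);
#' * segment mean = z + N(0, 0.15)         (active mean 1.0, inactive 0);
#' * promoter beta per CpG = clamp(0.55 - 0.3 z + N(0, 0.05) + N(0, 0.03)),
#'   the first noise term shared per patient, the second per CpG, clamped to
#'   \[0, 1\].
#'
#' @param cfg A [sim_config()].
#' @return list with `cohort` (an [omics_cohort()]) and `labels` (logical
#'   vector of true activity, named by patient).
#' @export
simulate_activity_omics <- function(cfg) {
  validate_sim_config(cfg)
  .seed_for(cfg, 307)
  n <- cfg$n_patients
  patient_ids <- sprintf("P%04d", seq_len(n))

  n_active <- round(cfg$frac_active * n)
  labels <- rep(FALSE, n)
  labels[sample.int(n, n_active)] <- TRUE
  names(labels) <- patient_ids

  z <- as.numeric(labels) + stats::rnorm(n, 0, 0.25)

  expr <- 10 + 2.2 * z + stats::rnorm(n, 0, 0.35)
  cnv <- z + stats::rnorm(n, 0, 0.15)

  n_cpg <- 14L
  cpg_ids <- sprintf("cg%07d", seq_len(n_cpg))
  patient_meth <- 0.55 - 0.3 * z + stats::rnorm(n, 0, 0.05)
  meth <- matrix(rep(patient_meth, each = n_cpg), nrow = n_cpg) +
    stats::rnorm(n_cpg * n, 0, 0.03)
  meth <- pmin(pmax(meth, 0), 1)
  dimnames(meth) <- list(cpg_ids, patient_ids)

  expr_mat <- matrix(expr, nrow = 1,
                     dimnames = list(cfg$regulator_id, patient_ids))
  cnv_mat <- matrix(cnv, nrow = 1,
                    dimnames = list(paste0(cfg$regulator_id, "_locus"),
                                    patient_ids))

  cohort <- omics_cohort(expression = expr_mat, cnv = cnv_mat,
                         methylation = meth, promoter_cpgs = cpg_ids,
                         patient_ids = patient_ids)
  list(cohort = cohort, labels = labels)
}

#' Construct an aligned multi-omic cohort object
#'
#' @param expression gene x patient matrix of log2 expression values.
#' @param cnv locus x patient matrix of copy-number segment means.
#' @param methylation CpG x patient matrix of beta-values in \[0, 1\].
#' @param promoter_cpgs CpG IDs mapped to the regulator's promoter; must all
#'   be rows of `methylation`.
#' @param patient_ids common patient ordering for all three matrices.
#' @return An `omics_cohort` list.
#' @export
omics_cohort <- function(expression, cnv, methylation, promoter_cpgs,
                         patient_ids) {
  for (m in list(expression, cnv, methylation)) {
    if (!identical(colnames(m), patient_ids)) {
      stop("patient IDs must be identical and identically ordered across ",
           "expression, cnv and methylation matrices")
    }
  }
  if (any(methylation < 0 | methylation > 1)) {
    stop("methylation beta-values must lie in [0, 1]")
  }
  if (length(promoter_cpgs) == 0L) stop("promoter_cpgs must be non-empty")
  structure(list(expression = expression, cnv = cnv,
                 methylation = methylation, promoter_cpgs = promoter_cpgs,
                 patient_ids = patient_ids),
            class = "omics_cohort")
}
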