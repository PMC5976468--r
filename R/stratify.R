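#' Per-patient promoter methylation summary
#'
#' Aggregates beta-values across the regulator's promoter CpGs into one
#' scalar per patient. The default is the unweighted mean; `median` and
#' `all_pass` (maximum, so "all CpGs below threshold" can be expressed as a
#' comparison of the summary) are available since no single aggregation rule
#' is canonical.
#'
#' @param cohort An [omics_cohort()].
#' @param aggregate One of "mean", "median", "all_pass".
#' @return Named numeric vector in \[0, 1\], one value per patient.
#' @export
promoter_methylation <- function(cohort,
                                 aggregate = c("mean", "median", "all_pass")) {
  aggregate <- match.arg(aggregate)
  missing <- setdiff(cohort$promoter_cpgs, rownames(cohort$methylation))
  if (length(missing) > 0L) {
    stop("promoter CpGs absent from methylation matrix: ",
         paste(missing, collapse = ", "))
  }
  m <- cohort$methylation[cohort$promoter_cpgs, , drop = FALSE]
  switch(aggregate,
         mean = colMeans(m),
         median = apply(m, 2, stats::median),
         all_pass = apply(m, 2, max))
}

#' Call regulator activity from the three omic criteria
#'
#' A patient is regulator-active iff all three hold:
#' expression of the regulator strictly above `expr_threshold` (default:
#' the cohort mean of the regulator's expression), copy-number segment mean
#' strictly above `cnv_threshold` (default 0.5), and promoter methylation
#' summary at most `beta_threshold` (default 0.4). Boundary handling is
#' exactly these strict/non-strict comparisons.
#'
#' @param cohort An [omics_cohort()].
#' @param regulator_gene_id Row of the expression matrix holding the
#'   regulator.
#' @param expr_threshold Expression cutoff; `NULL` (default) uses the cohort
#'   mean computed over all patients in the cohort.
#' @param cnv_threshold Copy-number cutoff (default 0.5).
#' @param beta_threshold Methylation cutoff (default 0.4).
#' @param meth_aggregate Aggregation rule passed to
#'   [promoter_methylation()].
#' @return An `activity_partition`: data.frame (patient_id, expr_high,
#'   cnv_amp, hypometh, active) with the thresholds used stored in
#'   `attr(, "thresholds")`.
#' @export
call_activity <- function(cohort, regulator_gene_id,
                          expr_threshold = NULL,
                          cnv_threshold = 0.5,
                          beta_threshold = 0.4,
                          meth_aggregate = "mean") {
  if (!regulator_gene_id %in% rownames(cohort$expression)) {
    stop("regulator '", regulator_gene_id, "' not in the expression matrix")
  }
  expr <- cohort$expression[regulator_gene_id, ]
  if (is.null(expr_threshold)) expr_threshold <- mean(expr)
  cnv <- cohort$cnv[1, ]
  beta <- promoter_methylation(cohort, aggregate = meth_aggregate)

  part <- data.frame(
    patient_id = cohort$patient_ids,
    expr_high = expr > expr_threshold,
    cnv_amp = cnv > cnv_threshold,
    hypometh = beta <= beta_threshold,
    stringsAsFactors = FALSE
  )
  part$active <- part$expr_high & part$cnv_amp & part$hypometh
  rownames(part) <- NULL
  attr(part, "thresholds") <- list(expr = expr_threshold,
                                   cnv = cnv_threshold,
                                   beta = beta_threshold,
                                   meth_aggregate = meth_aggregate)
  class(part) <- c("activity_partition", "data.frame")
  part
}

#' @export
print.activity_partition <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat("activity_partition:", sum(x$active), "active /", sum(!x$active),
      "inactive of", nrow(x), "patients\n")
  cat(sprintf("thresholds: expr > %.5f, cnv > %g, beta <= %g (%s)\n",
              th$expr, th$cnv, th$beta, th$meth_aggregate))
  invisible(x)
}
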