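#' Simulate a paired regulator-knockdown experiment
#'
#' Emulates two cell lines, each profiled once under scrambled-control and
#' once under regulator-siRNA conditions. The planted target gene loses
#' `per_line_effect` expression units in each siRNA sample, so its combined
#' (summed over cell lines) control-minus-siRNA difference is about twice
#' that and clears the 1.0 downregulation cutoff; all other genes have no
#' condition effect. Sample-level offsets are added so that the per-sample
#' centering step of the analysis is actually exercised.
#'
#' @param truth `planted_truth` naming the target gene.
#' @param cfg A [sim_config()].
#' @param per_line_effect Control-minus-siRNA drop of the target gene per
#'   cell line (default 0.9, combined ~1.8).
#' @param cell_lines Names of the two cell lines.
#' @return A `kd_experiment`: list of `expression` (gene x sample matrix) and
#'   `samples` (data.frame: sample, cell_line, condition).
#' @export
simulate_knockdown <- function(truth, cfg, per_line_effect = 0.9,
                               cell_lines = c("CL1", "CL2")) {
  validate_sim_config(cfg)
  .seed_for(cfg, 503)
  gene_ids <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  samples <- data.frame(
    sample = as.vector(t(outer(cell_lines, c("control", "siRNA"),
                               paste, sep = "_"))),
    cell_line = rep(cell_lines, each = 2),
    condition = rep(c("control", "siRNA"), length(cell_lines)),
    stringsAsFactors = FALSE
  )
  baseline <- stats::runif(cfg$n_genes, 4, 8)
  sample_offset <- stats::rnorm(nrow(samples), 0, 0.5)
  expr <- outer(baseline, sample_offset, "+") +
    matrix(stats::rnorm(cfg$n_genes * nrow(samples), 0, 0.15),
           nrow = cfg$n_genes)
  dimnames(expr) <- list(gene_ids, samples$sample)
  si <- samples$condition == "siRNA"
  expr[truth$target_gene_id, si] <- expr[truth$target_gene_id, si] -
    per_line_effect
  kd_experiment(expr, samples)
}

#' Construct a knockdown experiment object
#'
#' @param expression gene (or probe) x sample matrix.
#' @param samples data.frame with columns sample, cell_line, condition
#'   (condition in {"control", "siRNA"}); every cell line must have both
#'   conditions.
#' @return A `kd_experiment` list.
#' @export
kd_experiment <- function(expression, samples) {
  stopifnot(identical(colnames(expression), samples$sample))
  if (!all(samples$condition %in% c("control", "siRNA"))) {
    stop("condition must be 'control' or 'siRNA'")
  }
  tab <- table(samples$cell_line,
               factor(samples$condition, levels = c("control", "siRNA")))
  if (nrow(tab) < 1L) stop("at least one cell line required")
  if (any(tab != 1L)) {
    stop("each cell line needs exactly one control and one siRNA sample")
  }
  structure(list(expression = expression, samples = samples),
            class = "kd_experiment")
}
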