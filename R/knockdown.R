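#' Center each sample of an expression matrix at zero
#'
#' Per-sample location normalization: every column is shifted so its mean
#' (or median) is 0. Shift-invariant within a sample, so between-gene
#' differences are preserved.
#'
#' @param expr gene x sample matrix.
#' @param center "mean" (default) or "median".
#' @return Matrix of the same shape with centered columns.
#' @export
center_samples <- function(expr, center = c("mean", "median")) {
  center <- match.arg(center)
  loc <- switch(center,
                mean = colMeans(expr),
                median = apply(expr, 2, stats::median))
  sweep(expr, 2, loc, "-")
}

#' Combined knockdown difference per gene
#'
#' After per-sample centering, computes for each gene the control-minus-
#' siRNA difference in each cell line and combines across cell lines. The
#' default combination is the sum (so one cutoff spans both lines); "mean"
#' and "min" (both lines must exceed the per-line share) are alternatives.
#'
#' @param experiment A [kd_experiment()].
#' @param center Passed to [center_samples()].
#' @param combine "sum" (default), "mean" or "min".
#' @return Named numeric vector, one combined difference per gene/probe.
#' @export
combined_difference <- function(experiment, center = "mean",
                                combine = c("sum", "mean", "min")) {
  combine <- match.arg(combine)
  expr <- center_samples(experiment$expression, center = center)
  s <- experiment$samples
  lines <- unique(s$cell_line)
  diffs <- sapply(lines, function(cl) {
    ctrl <- s$sample[s$cell_line == cl & s$condition == "control"]
    si <- s$sample[s$cell_line == cl & s$condition == "siRNA"]
    if (length(ctrl) != 1L || length(si) != 1L) {
      stop("cell line ", cl, " lacks a control or siRNA sample")
    }
    expr[, ctrl] - expr[, si]
  })
  diffs <- matrix(diffs, nrow = nrow(expr),
                  dimnames = list(rownames(expr), lines))
  switch(combine,
         sum = rowSums(diffs),
         mean = rowMeans(diffs),
         min = apply(diffs, 1, min))
}

#' Genes downregulated upon regulator knockdown
#'
#' Genes whose combined control-minus-siRNA difference strictly exceeds the
#' cutoff (default 1.0). When several probes map to one gene, the gene's
#' combined difference is the maximum over its probes, and the gene appears
#' once.
#'
#' @param experiment A [kd_experiment()].
#' @param threshold Strict cutoff on the combined difference (default 1.0).
#' @param probe_map Optional named character vector mapping probe IDs (the
#'   matrix rownames) to gene IDs; identity when NULL.
#' @param ... Passed to [combined_difference()].
#' @return data.frame (gene_id, combined_diff) of unique downregulated
#'   genes, sorted by decreasing difference.
#' @export
downregulated_genes <- function(experiment, threshold = 1.0,
                                probe_map = NULL, ...) {
  cd <- combined_difference(experiment, ...)
  genes <- if (is.null(probe_map)) names(cd) else {
    unname(probe_map[names(cd)])
  }
  per_gene <- tapply(cd, genes, max)
  out <- data.frame(gene_id = names(per_gene),
                    combined_diff = as.numeric(per_gene),
                    stringsAsFactors = FALSE)
  out <- out[out$combined_diff > threshold, , drop = FALSE]
  out <- out[order(-out$combined_diff), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict eQTL pairs to knockdown-responsive target genes
#'
#' @param pairs data.frame of cis pairs with a `gene_id` column.
#' @param de_genes Character vector of downregulated gene IDs (or the
#'   data.frame from [downregulated_genes()]).
#' @return The subset of `pairs` whose gene is in `de_genes`.
#' @export
filter_pairs_by_de <- function(pairs, de_genes) {
  if (is.data.frame(de_genes)) de_genes <- de_genes$gene_id
  out <- pairs[pairs$gene_id %in% de_genes, , drop = FALSE]
  rownames(out) <- NULL
  out
}
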