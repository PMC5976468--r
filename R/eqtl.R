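#' Enumerate candidate cis SNP-gene pairs
#'
#' All same-chromosome pairs whose SNP position lies within `window_bp` of
#' the gene's TSS. Distance is SNP position minus TSS, strand-agnostic.
#'
#' @param variants data.frame (id, chrom, pos).
#' @param gene_positions data.frame (gene_id, chrom, tss).
#' @param window_bp Cis window in bp (default 1e6, the conventional local
#'   eQTL distance).
#' @return data.frame (snp_id, gene_id, distance).
#' @export
enumerate_cis_pairs <- function(variants, gene_positions, window_bp = 1e6) {
  out <- vector("list", nrow(gene_positions))
  for (i in seq_len(nrow(gene_positions))) {
    g <- gene_positions[i, ]
    d <- variants$pos - g$tss
    keep <- variants$chrom == g$chrom & abs(d) <= window_bp
    if (!any(keep)) next
    out[[i]] <- data.frame(snp_id = variants$id[keep],
                           gene_id = g$gene_id,
                           distance = d[keep],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(snp_id = character(), gene_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Additive-model association of one SNP with one gene
#'
#' Ordinary least squares of expression on allele dosage with an intercept,
#' computed in closed form, with a two-sided t-test on the slope at
#' `n - 2` degrees of freedom. This is the single-pair equivalent of the
#' matrix-operation eQTL scan. Missing values are dropped pairwise. A p
#' value underflowing to zero (perfect fits) is floored at the smallest
#' positive double so that downstream FDR adjustment stays in (0, 1].
#'
#' @param dosage Numeric vector of allele dosages (0/1/2; NA allowed).
#' @param expression Numeric vector of expression values, same length.
#' @return list(beta, t_stat, p_value, n) or, when the fit is impossible
#'   (fewer than 3 complete pairs, or constant dosage), list(skipped =
#'   reason).
#' @export
fit_additive <- function(dosage, expression) {
  stopifnot(length(dosage) == length(expression))
  ok <- !is.na(dosage) & !is.na(expression)
  g <- as.numeric(dosage[ok])
  y <- as.numeric(expression[ok])
  n <- length(g)
  if (n < 3L) return(list(skipped = "fewer than 3 complete observations"))
  sxx <- sum((g - mean(g))^2)
  if (sxx == 0) return(list(skipped = "monomorphic in group"))
  beta <- sum((g - mean(g)) * (y - mean(y))) / sxx
  resid <- y - mean(y) - beta * (g - mean(g))
  rss <- sum(resid^2)
  df <- n - 2L
  if (rss <= 0) {
    return(list(beta = beta, t_stat = Inf * sign(beta),
                p_value = .Machine$double.xmin, n = n))
  }
  se <- sqrt(rss / df / sxx)
  t_stat <- beta / se
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  list(beta = beta, t_stat = t_stat,
       p_value = max(p, .Machine$double.xmin), n = n)
}

#' One-way ANOVA across genotype classes
#'
#' Treats the dosage as a categorical factor (genotype classes 0/1/2) and
#' tests equality of class means, the genotype-class complement to the
#' additive trend test. Delegates to the standard linear-model ANOVA.
#' Pairwise two-sample t-tests between classes are returned alongside,
#' since "ANOVA" is sometimes used loosely for those.
#'
#' @param dosage,expression Numeric vectors (NA dropped pairwise).
#' @return list(F_stat, p_value, df, pairwise_t_p) or list(skipped =
#'   reason) when fewer than 2 classes have >= 2 observations each.
#' @export
fit_anova <- function(dosage, expression) {
  stopifnot(length(dosage) == length(expression))
  ok <- !is.na(dosage) & !is.na(expression)
  g <- factor(dosage[ok])
  y <- as.numeric(expression[ok])
  sizes <- table(g)
  usable <- sizes >= 2L
  if (sum(usable) < 2L) {
    return(list(skipped = "need >= 2 genotype classes with >= 2 patients"))
  }
  keep <- g %in% names(sizes)[usable]
  g <- droplevels(g[keep]); y <- y[keep]
  fit <- stats::lm(y ~ g)
  an <- stats::anova(fit)
  lv <- levels(g)
  pw <- list()
  for (i in seq_len(length(lv) - 1L)) {
    for (j in seq(i + 1L, length(lv))) {
      key <- paste(lv[i], lv[j], sep = "_vs_")
      pw[[key]] <- tryCatch(
        stats::t.test(y[g == lv[i]], y[g == lv[j]])$p.value,
        error = function(e) NA_real_
      )
    }
  }
  list(F_stat = an$`F value`[1], p_value = an$`Pr(>F)`[1],
       df = unname(an$Df[1:2]), pairwise_t_p = unlist(pw))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard BH: sort ascending, `adj_i = min_{j >= i}(p_j * m / j)`, cap at
#' 1, return in input order (delegated to [stats::p.adjust()] after
#' validating the input domain).
#'
#' @param p_values Numeric vector with entries in (0, 1].
#' @return Adjusted values in (0, 1], same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Cis-eQTL scan over one patient group
#'
#' Fits the additive model for every candidate cis pair restricted to the
#' given patients, adjusts p-values by Benjamini-Hochberg over *all* tested
#' pairs in the group (the output p threshold only prunes what is
#' reported, not the multiple-testing denominator), and returns the pairs
#' with `p < p_out_threshold`.
#'
#' @param geno `genotype_matrix`.
#' @param expression gene x patient matrix.
#' @param genes data.frame (gene_id, chrom, tss).
#' @param patients Character vector of patient IDs in the group.
#' @param group Label recorded in the output (e.g. "active").
#' @param window_bp Cis window (default 1e6).
#' @param p_out_threshold Raw-p reporting threshold (default 0.05).
#' @return data.frame of cis pairs (snp_id, gene_id, distance, beta,
#'   t_stat, p_value, fdr, group) with attributes `n_tested` (pairs that
#'   produced a fit) and `skipped` (pairs skipped, with reasons).
#' @export
scan_group <- function(geno, expression, genes, patients, group = "group",
                       window_bp = 1e6, p_out_threshold = 0.05) {
  if (length(patients) == 0L) stop("patient group is empty")
  if (!all(patients %in% geno$patient_ids) ||
      !all(patients %in% colnames(expression))) {
    stop("group patients missing from genotype or expression data")
  }
  cand <- enumerate_cis_pairs(geno$variants, genes, window_bp)
  dos <- geno$dosages[, patients, drop = FALSE]
  expr <- expression[, patients, drop = FALSE]

  m <- nrow(cand)
  beta <- t_stat <- p <- rep(NA_real_, m)
  skipped <- character(m)
  for (k in seq_len(m)) {
    fit <- fit_additive(dos[cand$snp_id[k], ], expr[cand$gene_id[k], ])
    if (!is.null(fit$skipped)) {
      skipped[k] <- fit$skipped
    } else {
      beta[k] <- fit$beta; t_stat[k] <- fit$t_stat; p[k] <- fit$p_value
    }
  }
  tested <- !is.na(p)
  fdr <- rep(NA_real_, m)
  fdr[tested] <- bh_fdr(p[tested])

  res <- cbind(cand, beta = beta, t_stat = t_stat, p_value = p, fdr = fdr,
               group = group, stringsAsFactors = FALSE)
  out <- res[tested & p < p_out_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- sum(tested)
  attr(out, "skipped") <- res[!tested, c("snp_id", "gene_id")]
  if (any(!tested)) {
    attr(out, "skipped")$reason <- skipped[!tested]
  }
  out
}

#' Compare per-group scans for group-unique associations
#'
#' A pair is significant in a group when its within-group FDR is below
#' `fdr_threshold`; uniqueness is judged at that same FDR rule in both
#' groups. Sets are keyed by (snp_id, gene_id) and are disjoint by
#' construction.
#'
#' @param active_pairs,inactive_pairs Outputs of [scan_group()] over the
#'   same candidate universe.
#' @param fdr_threshold Significance rule (default 0.01).
#' @return list(unique_to_active, unique_to_inactive, shared, rule).
#' @export
compare_groups <- function(active_pairs, inactive_pairs,
                           fdr_threshold = 0.01) {
  key <- function(df) paste(df$snp_id, df$gene_id, sep = "\r")
  sig_a <- active_pairs[!is.na(active_pairs$fdr) &
                          active_pairs$fdr < fdr_threshold, , drop = FALSE]
  sig_i <- inactive_pairs[!is.na(inactive_pairs$fdr) &
                            inactive_pairs$fdr < fdr_threshold, , drop = FALSE]
  ka <- key(sig_a); ki <- key(sig_i)
  list(
    unique_to_active = sig_a[!(ka %in% ki), , drop = FALSE],
    unique_to_inactive = sig_i[!(ki %in% ka), , drop = FALSE],
    shared = sig_a[ka %in% ki, , drop = FALSE],
    rule = sprintf("fdr < %g in-group, both groups", fdr_threshold)
  )
}
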