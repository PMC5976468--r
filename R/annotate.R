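#' Named genomic interval set
#'
#' Internal coordinates are 0-based half-open `[start, end)`, the BED
#' convention, and all annotation queries below take 0-based point
#' coordinates; VCF/annotation positions (1-based) are converted by the
#' ingest layer (`pos - 1`).
#'
#' @param intervals data.frame with columns chrom, start, end, name.
#' @param disjoint Require non-overlapping intervals per chromosome (TADs);
#'   violations are an error.
#' @return An `interval_set` (sorted by chrom, start).
#' @export
interval_set <- function(intervals, disjoint = FALSE) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) {
    stop("intervals must satisfy start < end (0-based half-open)")
  }
  intervals <- intervals[order(intervals$chrom, intervals$start), ]
  rownames(intervals) <- NULL
  if (disjoint) {
    for (ch in unique(intervals$chrom)) {
      sub <- intervals[intervals$chrom == ch, ]
      if (nrow(sub) > 1L &&
          any(sub$start[-1] < sub$end[-nrow(sub)])) {
        stop("intervals overlap on ", ch, " but were declared disjoint")
      }
    }
  }
  structure(list(intervals = intervals, disjoint = disjoint),
            class = "interval_set")
}

.as_granges <- function(iset) {
  df <- iset$intervals
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    name = df$name
  )
}

.containing_interval <- function(iset, chrom, pos0) {
  df <- iset$intervals
  hit <- which(df$chrom == chrom & df$start <= pos0 & pos0 < df$end)
  if (length(hit) == 0L) NA_character_ else df$name[hit[1]]
}

#' Do two genomic points share a TAD?
#'
#' A point sitting exactly on a boundary belongs to the interval whose
#' half-open range contains it (i.e. to the downstream TAD).
#'
#' @param tads An [interval_set()] with `disjoint = TRUE`.
#' @param point_a,point_b Lists or vectors `(chrom, pos)` with pos 0-based.
#' @return list(same_tad, tad_a, tad_b); `tad_*` is NA ("unassigned") when a
#'   point falls in no TAD, in which case `same_tad` is FALSE.
#' @export
same_tad <- function(tads, point_a, point_b) {
  if (!isTRUE(tads$disjoint)) {
    stop("TAD interval set must be validated as disjoint")
  }
  ta <- .containing_interval(tads, as.character(point_a[[1]]),
                             as.numeric(point_a[[2]]))
  tb <- .containing_interval(tads, as.character(point_b[[1]]),
                             as.numeric(point_b[[2]]))
  list(same_tad = !is.na(ta) && !is.na(tb) && ta == tb,
       tad_a = ta, tad_b = tb)
}

#' Peaks overlapping a gene's promoter window
#'
#' The promoter is a strand-aware window around the TSS: `upstream_bp`
#' toward the 5' side and `downstream_bp` toward the 3' side (so for a minus
#' strand gene "upstream" extends to higher coordinates).
#'
#' @param peaks An [interval_set()].
#' @param tss List/vector `(chrom, pos, strand)`; pos 0-based.
#' @param upstream_bp,downstream_bp Window extents (defaults 2000 / 500).
#' @return data.frame of overlapping peak intervals (possibly empty).
#' @export
promoter_overlap <- function(peaks, tss, upstream_bp = 2000L,
                             downstream_bp = 500L) {
  chrom <- as.character(tss[[1]])
  pos <- as.numeric(tss[[2]])
  strand <- as.character(tss[[3]])
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (strand == "+") {
    win_start <- pos - upstream_bp
    win_end <- pos + downstream_bp + 1
  } else {
    win_start <- pos - downstream_bp
    win_end <- pos + upstream_bp + 1
  }
  win <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(start = win_start + 1,
                                                 end = win_end))
  gr <- .as_granges(peaks)
  hits <- GenomicRanges::findOverlaps(gr, win)
  out <- peaks$intervals[S4Vectors_queryHits(hits), , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# queryHits without importing S4Vectors into the NAMESPACE surface
S4Vectors_queryHits <- function(hits) {
  as.data.frame(hits)$queryHits
}

#' Minor allele frequency per patient category
#'
#' The minor allele is fixed on the whole cohort (tie between the two
#' alleles broken to alt) and its frequency is then reported per category:
#' sum of minor-allele dosages over twice the number of non-missing
#' patients.
#'
#' @param geno `genotype_matrix`.
#' @param snp_id Variant ID.
#' @param grouping Named character/factor vector, names = patient IDs.
#' @return data.frame: category, maf, n_patients; plus attribute
#'   `minor_allele` ("ref"/"alt"). Empty categories are dropped with a
#'   warning.
#' @export
maf_by_group <- function(geno, snp_id, grouping) {
  dose <- geno$dosages[snp_id, ]
  if (is.null(names(grouping))) stop("grouping must be named by patient ID")
  grouping <- grouping[geno$patient_ids]
  if (anyNA(grouping)) {
    warning(sum(is.na(grouping)), " patients without a category are dropped")
  }
  alt_freq <- sum(dose, na.rm = TRUE) / (2 * sum(!is.na(dose)))
  minor_is_alt <- alt_freq <= 0.5  # tie broken to alt
  cats <- unique(stats::na.omit(as.character(grouping)))
  rows <- lapply(cats, function(cat) {
    d <- dose[!is.na(grouping) & grouping == cat]
    d <- d[!is.na(d)]
    if (length(d) == 0L) return(NULL)
    f_alt <- sum(d) / (2 * length(d))
    data.frame(category = cat,
               maf = if (minor_is_alt) f_alt else 1 - f_alt,
               n_patients = length(d), stringsAsFactors = FALSE)
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty)) warning("empty categories omitted")
  out <- do.call(rbind, rows[!empty])
  rownames(out) <- NULL
  attr(out, "minor_allele") <- if (minor_is_alt) "alt" else "ref"
  out
}

#' Genotype-by-clinical-feature association
#'
#' Cross-tabulates minor-allele carrier status (dominant coding: >= 1 minor
#' allele vs none) against a categorical clinical feature and tests
#' independence with Pearson's chi-square (no continuity correction). When
#' any expected cell count falls below 5 and the table is 2 x 2, Fisher's
#' exact test is used instead; for larger sparse tables the chi-square
#' result is kept and flagged.
#'
#' @param clinical data.frame with a logical `carrier` column and the
#'   feature column.
#' @param feature Name of the categorical feature column.
#' @return list(table, statistic, p_value, method, low_expected).
#' @export
genotype_feature_association <- function(clinical, feature) {
  f <- factor(clinical[[feature]])
  if (nlevels(f) < 2L) {
    stop("feature '", feature, "' has a single level; association undefined")
  }
  carrier <- factor(ifelse(clinical$carrier, "minor_carrier", "major_only"),
                    levels = c("major_only", "minor_carrier"))
  tab <- table(carrier, f, dnn = c("carrier", feature))
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  low_expected <- any(cs$expected < 5)
  if (low_expected && all(dim(tab) == 2L)) {
    ft <- stats::fisher.test(tab)
    return(list(table = tab, statistic = NA_real_, p_value = ft$p.value,
                method = "fisher", low_expected = TRUE))
  }
  list(table = tab, statistic = unname(cs$statistic),
       p_value = cs$p.value, method = "chisq", low_expected = low_expected)
}

#' Descriptive clinical comparisons for a focal variant
#'
#' Summaries mirroring a clinical characteristics table: age compared
#' between carrier groups with a two-sample t-test, stage with a chi-square
#' test, plus the per-group age five-number summary.
#'
#' @param clinical data.frame with carrier, age, stage columns.
#' @return list(age_summary, age_t_test_p, stage_association).
#' @export
clinical_summaries <- function(clinical) {
  by_carrier <- split(clinical$age, clinical$carrier)
  age_summary <- lapply(by_carrier, summary)
  age_p <- tryCatch(
    stats::t.test(age ~ carrier, data = clinical)$p.value,
    error = function(e) NA_real_
  )
  stage <- tryCatch(genotype_feature_association(clinical, "stage"),
                    error = function(e) NULL)
  list(age_summary = age_summary, age_t_test_p = age_p,
       stage_association = stage)
}
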