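#' Simulate TADs and regulator ChIP peaks around the planted locus
#'
#' Tiles the simulated chromosome with non-overlapping, sorted TADs whose
#' boundaries avoid the span between the planted variant and the target
#' gene's TSS, so both fall inside one TAD (named per the planted truth).
#' Also emits a small regulator ChIP peak set with one peak inside the
#' target gene's promoter window and a few decoy peaks elsewhere.
#'
#' @param truth `planted_truth`.
#' @param cfg A [sim_config()].
#' @param geno The matching `genotype_matrix`.
#' @param genes Gene annotation from [simulate_genes()].
#' @param n_tads Approximate number of TADs (default 8).
#' @return list of `tads` and `peaks`, both [interval_set()] objects
#'   (0-based half-open coordinates).
#' @export
simulate_intervals <- function(truth, cfg, geno, genes, n_tads = 8L) {
  validate_sim_config(cfg)
  .seed_for(cfg, 701)
  var <- geno$variants[geno$variants$id == truth$motif_snp_id, ]
  tag <- geno$variants[geno$variants$id == truth$tag_snp_id, ]
  tss <- genes$tss[genes$gene_id == truth$target_gene_id]
  chrom <- var$chrom

  # protected span (0-based) that no TAD boundary may cut
  lo <- min(var$pos, tag$pos, tss) - 1L - 5000L
  hi <- max(var$pos, tag$pos, tss) - 1L + 5000L

  breaks <- sort(sample.int(cfg$chrom_length - 1L, n_tads - 1L))
  breaks <- breaks[breaks < lo | breaks > hi]
  edges <- unique(c(0L, breaks, as.integer(cfg$chrom_length)))
  tads <- data.frame(
    chrom = chrom,
    start = edges[-length(edges)],
    end = edges[-1],
    name = sprintf("TAD%02d", seq_len(length(edges) - 1L)),
    stringsAsFactors = FALSE
  )
  planted <- which(tads$start <= (tag$pos - 1L) & (tag$pos - 1L) < tads$end)
  tads$name[planted] <- truth$tad_id

  # one promoter peak on the (+ strand) target gene + decoys
  prom_peak <- data.frame(
    chrom = chrom, start = tss - 1L - 800L, end = tss - 1L + 300L,
    name = "peak_promoter", stringsAsFactors = FALSE
  )
  decoy_start <- sort(sample.int(cfg$chrom_length - 2000L, 3L))
  decoys <- data.frame(
    chrom = chrom, start = decoy_start, end = decoy_start + 1000L,
    name = sprintf("peak_decoy%02d", seq_along(decoy_start)),
    stringsAsFactors = FALSE
  )
  peaks <- rbind(prom_peak, decoys)
  peaks <- peaks[order(peaks$start), ]
  rownames(peaks) <- NULL

  list(tads = interval_set(tads, disjoint = TRUE),
       peaks = interval_set(peaks))
}

#' Simulate a clinical table linked to the planted variant
#'
#' Assigns race, tumor location, stage, and age at diagnosis per patient.
#' Tumor laterality is generated dependent on minor-allele carrier status of
#' the planted tag SNP (carriers are right-lung predominant), so the
#' genotype-location association test has a real signal to find; stage and
#' age are independent of genotype. Race frequencies differ between
#' carriers and non-carriers.
#'
#' @param geno `genotype_matrix`.
#' @param truth `planted_truth`.
#' @param cfg A [sim_config()].
#' @return data.frame: patient_id, race, location, laterality, stage, age,
#'   carrier (logical, >= 1 minor allele of the tag SNP).
#' @export
simulate_clinical <- function(geno, truth, cfg) {
  validate_sim_config(cfg)
  .seed_for(cfg, 809)
  dose <- geno$dosages[truth$tag_snp_id, ]
  n <- length(dose)
  # alt is the minor allele for the planted SNP (MAF <= 0.5 by construction)
  carrier <- dose >= 1L

  race <- ifelse(
    stats::runif(n) < ifelse(carrier, 0.36, 0.08), "black",
    ifelse(stats::runif(n) < 0.94, "white", "asian")
  )
  p_right <- ifelse(carrier, 0.76, 0.53)
  side <- ifelse(stats::runif(n) < p_right, "right", "left")
  lobe <- sample(c("lower", "upper"), n, replace = TRUE)
  location <- paste(side, lobe, sep = "-")
  stage <- sample(c("i", "ii", "iii", "iv"), n, replace = TRUE,
                  prob = c(0.5, 0.31, 0.17, 0.02))
  age <- round(pmin(pmax(stats::rnorm(n, 67, 8), 39), 90))

  data.frame(patient_id = geno$patient_ids, race = race,
             location = location, laterality = side, stage = stage,
             age = age, carrier = carrier, stringsAsFactors = FALSE)
}
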