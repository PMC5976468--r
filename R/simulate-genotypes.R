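#' Simulate a genotype matrix with a planted perfect-LD tag/indel pair
#'
#' Draws Hardy-Weinberg genotype dosages (0/1/2 copies of the alt allele) at
#' `n_snps` array SNPs with per-SNP minor allele frequencies uniform over
#' `maf_range`, then plants one tag SNP (at the midpoint MAF of the range)
#' together with an off-array insertion variant whose dosage vector is
#' elementwise identical to the tag's (perfect LD, r^2 = 1). The indel mimics
#' a variant discoverable only through LD: its alt allele is one base longer
#' than its ref (T -> TA) and it is excluded from the association scan via
#' the `on_array` flag.
#'
#' @param cfg A [sim_config()].
#' @return A list with components
#'   * `geno`: a `genotype_matrix` — list of `dosages` (variant x patient
#'     integer matrix), `variants` (data.frame: id, chrom, pos 1-based, ref,
#'     alt, on_array), and `patient_ids`;
#'   * `truth`: a `planted_truth` record (tag/motif/target ids, effect sizes).
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  .seed_for(cfg, 101)
  n <- cfg$n_patients
  patient_ids <- sprintf("P%04d", seq_len(n))
  chrom <- "chr1"

  pos <- sort(sample.int(cfg$chrom_length - 1000L, cfg$n_snps))
  maf <- stats::runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])

  # Tag SNP: central position, midpoint MAF; redraw until polymorphic.
  tag_idx <- ceiling(cfg$n_snps / 2)
  maf[tag_idx] <- mean(cfg$maf_range)

  dos <- matrix(0L, nrow = cfg$n_snps, ncol = n)
  for (i in seq_len(cfg$n_snps)) {
    g <- stats::rbinom(n, 2L, maf[i])
    if (i == tag_idx) {
      while (length(unique(g)) < 2L) g <- stats::rbinom(n, 2L, maf[i])
    }
    dos[i, ] <- g
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  ids <- sprintf("snp%04d", seq_len(cfg$n_snps))
  variants <- data.frame(
    id = ids, chrom = chrom, pos = pos, ref = ref, alt = alt,
    on_array = TRUE, stringsAsFactors = FALSE
  )

  # Off-array insertion partner ~1.2 kb downstream of the tag SNP, identical
  # dosages (perfect LD).
  motif_pos <- pos[tag_idx] + 1234L
  motif_var <- data.frame(
    id = "indel0001", chrom = chrom, pos = motif_pos,
    ref = "T", alt = "TA", on_array = FALSE, stringsAsFactors = FALSE
  )
  ord_pos <- c(pos, motif_pos)
  ord <- order(ord_pos)
  variants <- rbind(variants, motif_var)[ord, ]
  dos <- rbind(dos, dos[tag_idx, , drop = TRUE])[ord, , drop = FALSE]
  rownames(dos) <- variants$id
  colnames(dos) <- patient_ids
  rownames(variants) <- NULL

  geno <- genotype_matrix(dos, variants, patient_ids)
  truth <- structure(list(
    tag_snp_id = ids[tag_idx],
    motif_snp_id = "indel0001",
    target_gene_id = sprintf("GENE%03d", 1L),
    beta_active = cfg$effect_beta,
    beta_inactive = 0,
    tad_id = "TAD_planted"
  ), class = "planted_truth")

  list(geno = geno, truth = truth)
}

#' Construct a genotype matrix object
#'
#' @param dosages variant x patient matrix with entries in {0, 1, 2} (NA
#'   allowed for missing genotypes).
#' @param variants data.frame with columns id, chrom, pos (1-based), ref, alt
#'   and optionally on_array.
#' @param patient_ids character vector matching `ncol(dosages)`.
#' @return A `genotype_matrix` list.
#' @export
genotype_matrix <- function(dosages, variants, patient_ids) {
  stopifnot(nrow(dosages) == nrow(variants),
            ncol(dosages) == length(patient_ids))
  ok <- dosages %in% c(0L, 1L, 2L) | is.na(dosages)
  if (!all(ok)) stop("dosages must be in {0, 1, 2} or NA")
  if (any(variants$pos < 1)) stop("variant positions are 1-based (pos >= 1)")
  if (any(!nzchar(variants$ref)) || any(!nzchar(variants$alt))) {
    stop("ref/alt alleles must be non-empty")
  }
  if (is.null(variants$on_array)) variants$on_array <- TRUE
  structure(list(dosages = dosages, variants = variants,
                 patient_ids = patient_ids),
            class = "genotype_matrix")
}

#' Subset a genotype matrix to array-genotyped variants
#'
#' @param geno A `genotype_matrix`.
#' @return A `genotype_matrix` restricted to variants with `on_array = TRUE`.
#' @export
array_variants <- function(geno) {
  keep <- geno$variants$on_array
  genotype_matrix(geno$dosages[keep, , drop = FALSE],
                  geno$variants[keep, , drop = FALSE],
                  geno$patient_ids)
}

#' Simulate gene annotation (TSS positions) for the synthetic cohort
#'
#' Places `n_genes` genes on the simulated chromosome. The planted target
#' gene's TSS is put within 100 kb of the tag SNP so the pair is comfortably
#' inside the 1 Mb cis window; the remaining genes are uniform over the
#' chromosome.
#'
#' @param cfg A [sim_config()].
#' @param truth A `planted_truth` from [simulate_genotypes()].
#' @param geno The matching `genotype_matrix`.
#' @return data.frame with columns gene_id, chrom, tss (1-based), strand.
#' @export
simulate_genes <- function(cfg, truth, geno) {
  .seed_for(cfg, 211)
  tag <- geno$variants[geno$variants$id == truth$tag_snp_id, ]
  tss <- sample.int(cfg$chrom_length - 5000L, cfg$n_genes) + 2000L
  tss[1] <- tag$pos + sample(2e4:1e5, 1L)  # target gene near the tag SNP
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  strand[1] <- "+"
  data.frame(
    gene_id = sprintf("GENE%03d", seq_len(cfg$n_genes)),
    chrom = tag$chrom, tss = as.integer(tss), strand = strand,
    stringsAsFactors = FALSE
  )
}
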