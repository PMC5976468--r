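#' Simulate a binding-motif flank and PWM around the planted indel
#'
#' Emits a 59 nt flanking sequence (variant position +/- 29 nt) centered on
#' the planted insertion variant, together with an 8 bp PWM whose consensus
#' is embedded in the flank such that the reference allele completes the
#' motif and the one-base insertion disrupts it. The embedded consensus
#' carries the variant's reference base at its 4th position, so every
#' placement covering the variant scores strictly lower on the alternate
#' (lengthened) sequence.
#'
#' @param truth `planted_truth` from [simulate_genotypes()].
#' @param cfg A [sim_config()].
#' @param geno The matching `genotype_matrix` (for the variant's position
#'   and alleles).
#' @param flank_radius Nucleotides on each side of the variant (default 29,
#'   i.e. a 59 nt reference flank).
#' @return list with `flank` (character, reference allele sequence), `pwm`
#'   ([pwm_matrix()]), and `placement` (variant_offset in the flank, 1-based;
#'   flank_start genome coordinate, 1-based; ref; alt).
#' @export
simulate_sequence_and_pwm <- function(truth, cfg, geno, flank_radius = 29L) {
  validate_sim_config(cfg)
  .seed_for(cfg, 601)
  var <- geno$variants[geno$variants$id == truth$motif_snp_id, ]
  if (nrow(var) != 1L) stop("motif variant not found in genotype matrix")

  consensus <- "CATTGTTC"  # SOX/HMG-like AT-rich core; variant base = pos 4
  w <- nchar(consensus)
  var_pos_in_motif <- 4L
  stopifnot(substr(consensus, var_pos_in_motif, var_pos_in_motif) ==
              substr(var$ref, 1, 1))

  flank_len <- 2L * flank_radius + 1L
  bases <- c("A", "C", "G", "T")
  flank <- sample(bases, flank_len, replace = TRUE)
  variant_offset <- flank_radius + 1L
  motif_start <- variant_offset - var_pos_in_motif + 1L
  flank[motif_start:(motif_start + w - 1L)] <- strsplit(consensus, "")[[1]]
  flank <- paste(flank, collapse = "")

  counts <- matrix(5, nrow = 4, ncol = w,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  cons_idx <- match(strsplit(consensus, "")[[1]], bases)
  for (j in seq_len(w)) counts[cons_idx[j], j] <- 85
  pwm <- pwm_matrix(counts)

  list(
    flank = flank,
    pwm = pwm,
    placement = list(
      variant_offset = variant_offset,
      flank_start = as.integer(var$pos - flank_radius),
      chrom = var$chrom,
      ref = var$ref,
      alt = var$alt
    )
  )
}
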