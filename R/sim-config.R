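#' Simulation configuration for synthetic cohorts
#'
#' Bundles every tunable of the synthetic-data generator. The defaults define
#' the reference study conditions used throughout the package's calibration
#' and power checks: 300 patients with half of them regulator-active, a
#' planted conditional eQTL of 0.8 residual standard deviations per alt
#' allele at minor allele frequency 0.3, and a single 3 Mb chromosome.
#'
#' @param n_patients Number of patients in the cohort (>= 2).
#' @param frac_active Fraction of patients that are truly regulator-active,
#'   strictly inside (0, 1).
#' @param n_snps Number of array-genotyped SNPs (the planted perfect-LD indel
#'   partner is added on top of these and flagged as off-array).
#' @param n_genes Number of expressed genes, including the planted target.
#' @param maf_range Length-2 numeric, lower/upper bound for per-SNP minor
#'   allele frequencies, each in (0, 0.5]. The planted tag SNP uses the
#'   midpoint of this range.
#' @param effect_beta Additive effect of the planted variant on the target
#'   gene in regulator-active patients, in expression units per alt allele.
#'   Inactive patients carry no genotype effect.
#' @param noise_sd Residual standard deviation of expression noise (> 0).
#' @param n_null_pairs Number of independent null SNP-gene pairs generated by
#'   [null_pvalues()] for type-I-error calibration.
#' @param seed Integer seed; every generator derives its stream from it, so an
#'   identical config reproduces bit-identical outputs.
#' @param chrom_length Length of the simulated chromosome in bp.
#' @param regulator_id Row name used for the regulator in the omics matrices.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 100, seed = 7)
#' cfg$frac_active
sim_config <- function(n_patients = 300L,
                       frac_active = 0.5,
                       n_snps = 30L,
                       n_genes = 15L,
                       maf_range = c(0.2, 0.4),
                       effect_beta = 0.8,
                       noise_sd = 1.0,
                       n_null_pairs = 5000L,
                       seed = 1L,
                       chrom_length = 3e6,
                       regulator_id = "REG1") {
  cfg <- list(
    n_patients = as.integer(n_patients),
    frac_active = frac_active,
    n_snps = as.integer(n_snps),
    n_genes = as.integer(n_genes),
    maf_range = as.numeric(maf_range),
    effect_beta = effect_beta,
    noise_sd = noise_sd,
    n_null_pairs = as.integer(n_null_pairs),
    seed = as.integer(seed),
    chrom_length = as.numeric(chrom_length),
    regulator_id = regulator_id
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(n_patients = cfg$n_patients, n_snps = cfg$n_snps,
              n_genes = cfg$n_genes, n_null_pairs = cfg$n_null_pairs)
  if (any(counts < 1L)) {
    stop("all counts must be >= 1; offending: ",
         paste(names(counts)[counts < 1L], collapse = ", "))
  }
  if (cfg$n_patients < 2L) {
    stop("n_patients must be >= 2 (degenerate cohort)")
  }
  if (!(cfg$frac_active > 0 && cfg$frac_active < 1)) {
    stop("frac_active must lie strictly inside (0, 1)")
  }
  if (length(cfg$maf_range) != 2L ||
      any(cfg$maf_range <= 0) || any(cfg$maf_range > 0.5) ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("maf_range must be an increasing pair within (0, 0.5]")
  }
  if (!(cfg$noise_sd > 0)) stop("noise_sd must be > 0")
  if (cfg$chrom_length < 1e4) stop("chrom_length implausibly small")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_patients, "patients (frac_active =", x$frac_active,
      "),", x$n_snps, "SNPs x", x$n_genes, "genes, beta_active =",
      x$effect_beta, ", seed =", x$seed, "\n")
  invisible(x)
}

# Per-generator seed offsets: each generator owns a deterministic stream
# derived from cfg$seed, so individual generators are reproducible in
# isolation and in any calling order. Offsets stay well below 2^31.
.seed_for <- function(cfg, offset) {
  s <- (as.numeric(cfg$seed) + offset) %% 2147483647
  set.seed(as.integer(s))
}
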