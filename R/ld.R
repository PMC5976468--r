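#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Classical two-locus LD from binary haplotype vectors (1 = alt allele):
#' `D = p_AB - p_A p_B`; `D' = D / Dmax` with
#' `Dmax = min(p_A (1 - p_B), (1 - p_A) p_B)` when `D > 0` and
#' `min(p_A p_B, (1 - p_A)(1 - p_B))` otherwise;
#' `r^2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`.
#'
#' @param hapA,hapB Equal-length binary vectors of per-haplotype alleles.
#' @return An `ld_result`: list(D, D_prime, r2, p_A, p_B, n_haplotypes,
#'   method = "haplotype").
#' @export
ld_from_haplotypes <- function(hapA, hapB) {
  stopifnot(length(hapA) == length(hapB), length(hapA) >= 2L)
  if (!all(hapA %in% c(0, 1)) || !all(hapB %in% c(0, 1))) {
    stop("haplotype vectors must be binary (0/1)")
  }
  pA <- mean(hapA); pB <- mean(hapB)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    stop("LD undefined: at least one locus is monomorphic")
  }
  pAB <- mean(hapA == 1 & hapB == 1)
  D <- pAB - pA * pB
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  D_prime <- if (D == 0) 0 else D / Dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(D = D, D_prime = D_prime, r2 = r2, p_A = pA, p_B = pB,
                 n_haplotypes = length(hapA), method = "haplotype"),
            class = "ld_result")
}

# log-likelihood of two-locus genotype data given haplotype frequencies
# f = c(f11, f10, f01, f00); counts n[i+1, j+1] = # individuals with
# dosages (i, j)
.two_locus_loglik <- function(f, n) {
  f11 <- f[1]; f10 <- f[2]; f01 <- f[3]; f00 <- f[4]
  # genotype-pair probabilities under random union of haplotypes
  pr <- matrix(0, 3, 3)
  pr[1, 1] <- f00^2
  pr[1, 2] <- 2 * f00 * f01
  pr[1, 3] <- f01^2
  pr[2, 1] <- 2 * f00 * f10
  pr[2, 2] <- 2 * f11 * f00 + 2 * f10 * f01
  pr[2, 3] <- 2 * f11 * f01
  pr[3, 1] <- f10^2
  pr[3, 2] <- 2 * f11 * f10
  pr[3, 3] <- f11^2
  keep <- n > 0
  if (any(pr[keep] <= 0)) return(-Inf)
  sum(n[keep] * log(pr[keep]))
}

#' Two-locus haplotype frequencies from unphased genotypes (EM)
#'
#' Standard expectation-maximization over the four haplotype classes. All
#' genotype combinations are phase-unambiguous except the double
#' heterozygote, whose coupling/repulsion split is re-estimated each
#' iteration. Initialization is at linkage equilibrium (products of allele
#' frequencies), which is deterministic and breaks the symmetric
#' double-heterozygote likelihood toward D = 0.
#'
#' @param genoA,genoB Dosage vectors in {0, 1, 2} (NA dropped pairwise).
#' @param tol Convergence threshold on the max frequency change
#'   (default 1e-8).
#' @param max_iter Iteration cap (default 1000); hitting it sets
#'   `converged = FALSE` with a warning.
#' @return An `ld_result` with `freq = c(f11, f10, f01, f00)` (index 1 =
#'   alt allele), `loglik` trace (one value per iteration, non-decreasing),
#'   `iterations`, `converged`, `ambiguous` (TRUE when every informative
#'   individual is a double heterozygote), plus D, D', r2 derived from the
#'   final frequencies.
#' @export
em_haplotype_freq <- function(genoA, genoB, tol = 1e-8, max_iter = 1000L) {
  ok <- !is.na(genoA) & !is.na(genoB)
  gA <- as.integer(genoA[ok]); gB <- as.integer(genoB[ok])
  if (length(gA) < 2L) stop("need >= 2 individuals with complete genotypes")
  if (!all(gA %in% 0:2) || !all(gB %in% 0:2)) {
    stop("dosages must be in {0, 1, 2}")
  }
  if (all(gA == 0L) || all(gA == 2L) || all(gB == 0L) || all(gB == 2L)) {
    stop("LD undefined: at least one locus is monomorphic")
  }
  n <- matrix(0, 3, 3)
  for (k in seq_along(gA)) {
    n[gA[k] + 1L, gB[k] + 1L] <- n[gA[k] + 1L, gB[k] + 1L] + 1
  }
  N <- sum(n)
  pA <- mean(gA) / 2; pB <- mean(gB) / 2
  f <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  ambiguous <- sum(n) == n[2, 2]

  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    loglik <- c(loglik, .two_locus_loglik(f, n))
    denom <- f[1] * f[4] + f[2] * f[3]
    w <- if (denom > 0) f[1] * f[4] / denom else 0.5  # coupling share
    # expected haplotype counts
    c11 <- 2 * n[3, 3] + n[3, 2] + n[2, 3] + w * n[2, 2]
    c10 <- 2 * n[3, 1] + n[3, 2] + n[2, 1] + (1 - w) * n[2, 2]
    c01 <- 2 * n[1, 3] + n[1, 2] + n[2, 3] + (1 - w) * n[2, 2]
    c00 <- 2 * n[1, 1] + n[1, 2] + n[2, 1] + w * n[2, 2]
    f_new <- c(c11, c10, c01, c00) / (2 * N)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("EM did not converge within ", max_iter,
                          " iterations")
  if (ambiguous) warning("all individuals are double heterozygotes; ",
                         "phase is not identifiable and the equilibrium ",
                         "initialization decides the tie")

  f11 <- f[1]
  pA_hat <- f[1] + f[2]; pB_hat <- f[1] + f[3]
  D <- f11 - pA_hat * pB_hat
  Dmax <- if (D > 0) min(pA_hat * (1 - pB_hat), (1 - pA_hat) * pB_hat) else
    min(pA_hat * pB_hat, (1 - pA_hat) * (1 - pB_hat))
  D_prime <- if (D == 0 || Dmax == 0) 0 else D / Dmax
  denom_r <- pA_hat * (1 - pA_hat) * pB_hat * (1 - pB_hat)
  r2 <- if (denom_r > 0) D^2 / denom_r else NA_real_
  structure(list(D = D, D_prime = D_prime, r2 = r2,
                 p_A = pA_hat, p_B = pB_hat,
                 freq = stats::setNames(f, c("f11", "f10", "f01", "f00")),
                 loglik = loglik, iterations = length(loglik),
                 converged = converged, ambiguous = ambiguous,
                 method = "em"),
            class = "ld_result")
}

#' Strong-LD partners of focal SNPs
#'
#' For each focal variant, computes r^2 against every same-chromosome
#' variant within `window_bp` (EM haplotype frequencies from the unphased
#' dosages, or direct haplotype counting when a phased haplotype matrix is
#' supplied) and keeps partners with `r2 > r2_threshold`.
#'
#' @param geno `genotype_matrix`.
#' @param focal_snps Character vector of focal variant IDs.
#' @param r2_threshold Strict r^2 cutoff (default 0.8).
#' @param window_bp Search window around the focal variant (default
#'   250000).
#' @param haplotypes Optional haplotype x variant binary matrix (2 rows per
#'   patient) with variant IDs as column names; when given, LD is computed
#'   by direct counting instead of EM.
#' @return data.frame (focal, partner, pos_focal, pos_partner, D_prime,
#'   r2, method), one row per passing partner.
#' @export
strong_ld_partners <- function(geno, focal_snps, r2_threshold = 0.8,
                               window_bp = 250000, haplotypes = NULL) {
  v <- geno$variants
  rows <- list()
  for (fs in focal_snps) {
    fv <- v[v$id == fs, ]
    if (nrow(fv) != 1L) stop("focal SNP '", fs, "' not found")
    cand <- v[v$chrom == fv$chrom & v$id != fs &
                abs(v$pos - fv$pos) <= window_bp, ]
    for (k in seq_len(nrow(cand))) {
      res <- tryCatch({
        if (is.null(haplotypes)) {
          em_haplotype_freq(geno$dosages[fs, ],
                            geno$dosages[cand$id[k], ])
        } else {
          ld_from_haplotypes(haplotypes[, fs], haplotypes[, cand$id[k]])
        }
      }, error = function(e) NULL, warning = function(w) {
        suppressWarnings(
          if (is.null(haplotypes)) {
            em_haplotype_freq(geno$dosages[fs, ],
                              geno$dosages[cand$id[k], ])
          } else NULL
        )
      })
      if (is.null(res) || is.na(res$r2) || res$r2 <= r2_threshold) next
      rows[[length(rows) + 1L]] <- data.frame(
        focal = fs, partner = cand$id[k],
        pos_focal = fv$pos, pos_partner = cand$pos[k],
        D_prime = res$D_prime, r2 = res$r2, method = res$method,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(focal = character(), partner = character(),
                      pos_focal = numeric(), pos_partner = numeric(),
                      D_prime = numeric(), r2 = numeric(),
                      method = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
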