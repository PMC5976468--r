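test_that("haplotype LD reproduces hand-computed D, D-prime, r2", {
  # counts AB=40, Ab=10, aB=10, ab=40 out of 100 haplotypes
  hapA <- rep(c(1, 1, 0, 0), times = c(40, 10, 10, 40))
  hapB <- rep(c(1, 0, 1, 0), times = c(40, 10, 10, 40))
  ld <- ld_from_haplotypes(hapA, hapB)
  expect_equal(ld$D, 0.15)
  expect_equal(ld$D_prime, 0.6)
  expect_equal(ld$r2, 0.36)

  same <- ld_from_haplotypes(c(1, 0, 1, 0, 1), c(1, 0, 1, 0, 1))
  expect_equal(same$r2, 1)
  expect_equal(abs(same$D_prime), 1)

  # exact linkage equilibrium: p_AB = p_A * p_B
  eqA <- rep(c(1, 1, 0, 0), times = c(25, 25, 25, 25))
  eqB <- rep(c(1, 0, 1, 0), times = c(25, 25, 25, 25))
  eq <- ld_from_haplotypes(eqA, eqB)
  expect_equal(eq$D, 0)
  expect_equal(eq$r2, 0)

  expect_error(ld_from_haplotypes(c(1, 1, 1), c(0, 1, 0)), "monomorphic")
})

test_that("allele relabeling negates D and D-prime but preserves r2", {
  set.seed(47)
  for (i in 1:30) {
    n <- 200
    hA <- rbinom(n, 1, runif(1, 0.2, 0.8))
    hB <- ifelse(runif(n) < 0.7, hA, rbinom(n, 1, 0.5))
    if (var(hA) == 0 || var(hB) == 0) next
    ld <- ld_from_haplotypes(hA, hB)
    sw <- ld_from_haplotypes(1 - hA, hB)
    expect_equal(sw$D, -ld$D, tolerance = 1e-12)
    expect_equal(sw$D_prime, -ld$D_prime, tolerance = 1e-12)
    expect_equal(sw$r2, ld$r2, tolerance = 1e-12)
  }
})

test_that("EM equals direct counting when no double heterozygotes exist", {
  gA <- c(0, 0, 2, 2, 1, 0)
  gB <- c(0, 0, 2, 2, 2, 1)   # no (1,1) individual: phase known
  em <- em_haplotype_freq(gA, gB)
  # direct haplotype counts: each individual contributes 2 haplotypes
  # (0,0)x2 -> 4x h00; (2,2)x2 -> 4x h11; (1,2) -> h11+h01; (0,1) -> h00+h01
  expect_equal(unname(em$freq),
               c(5, 0, 2, 5) / 12, tolerance = 1e-6)
  expect_true(em$converged)
})

test_that("EM recovers generating haplotype frequencies and climbs monotonically", {
  set.seed(53)
  f_true <- c(0.4, 0.1, 0.1, 0.4)  # (11, 10, 01, 00)
  n <- 500
  haps <- sample(1:4, 2 * n, replace = TRUE, prob = f_true)
  hA <- as.integer(haps %in% c(1, 2))
  hB <- as.integer(haps %in% c(1, 3))
  gA <- hA[seq(1, 2 * n, 2)] + hA[seq(2, 2 * n, 2)]
  gB <- hB[seq(1, 2 * n, 2)] + hB[seq(2, 2 * n, 2)]
  em <- em_haplotype_freq(gA, gB)
  expect_true(all(abs(em$freq - f_true) < 0.05))
  expect_equal(sum(em$freq), 1, tolerance = 1e-9)
  expect_true(all(diff(em$loglik) >= -1e-10))
})

test_that("all-double-heterozygote data is flagged ambiguous", {
  expect_warning(em <- em_haplotype_freq(rep(1, 10), rep(1, 10)),
                 "double heterozygotes")
  expect_true(em$ambiguous)
  # equilibrium initialization leaves the symmetric tie at D = 0
  expect_equal(em$D, 0, tolerance = 1e-9)
})

test_that("phased and EM-based r2 agree on synthetic genotypes", {
  set.seed(59)
  n <- 600
  for (rho in c(0.95, 0.6)) {
    hA <- rbinom(2 * n, 1, 0.4)
    hB <- ifelse(runif(2 * n) < rho, hA, rbinom(2 * n, 1, 0.4))
    ld_h <- ld_from_haplotypes(hA, hB)
    gA <- hA[seq(1, 2 * n, 2)] + hA[seq(2, 2 * n, 2)]
    gB <- hB[seq(1, 2 * n, 2)] + hB[seq(2, 2 * n, 2)]
    ld_e <- em_haplotype_freq(gA, gB)
    expect_lt(abs(ld_h$r2 - ld_e$r2), 0.02)
  }
})

test_that("strong-LD search honors the r2 threshold and window", {
  sim <- small_sim(seed = 61)
  out <- strong_ld_partners(sim$geno, sim$truth$tag_snp_id)
  hit <- out[out$partner == sim$truth$motif_snp_id, ]
  expect_equal(nrow(hit), 1)
  expect_gt(hit$r2, 0.999)

  none <- strong_ld_partners(sim$geno, sim$truth$tag_snp_id,
                             r2_threshold = 1.01)
  expect_equal(nrow(none), 0)

  narrow <- strong_ld_partners(sim$geno, sim$truth$tag_snp_id,
                               window_bp = 100)
  expect_false(sim$truth$motif_snp_id %in% narrow$partner)
})

test_that("allele substitution splices ref to alt, including indels", {
  out <- apply_allele("ACGTACG", 4, "T", "TA")
  expect_equal(out$ref_seq, "ACGTACG")
  expect_equal(out$alt_seq, "ACGTAACG")
  expect_equal(apply_allele("ACGT", 2, "C", "C")$alt_seq, "ACGT")
  expect_error(apply_allele("ACGTACG", 3, "T", "A"), "mismatch")
})

test_that("PWM scoring follows the log2-odds definition", {
  flat <- pwm_matrix(matrix(0.25, 4, 5), pseudocount = 0)
  expect_equal(pwm_score("ACGTA", flat), 0)
  expect_equal(pwm_score("NNNNN", flat), 0)

  counts <- matrix(c(8, 1, 1, 0,
                     0, 9, 1, 0,
                     1, 0, 0, 9), nrow = 4)
  pwm <- pwm_matrix(counts, pseudocount = 0.8)
  hand <- function(idx) {
    sum(sapply(seq_along(idx), function(j) {
      log2(((counts[idx[j], j] + 0.2) / 10.8) / 0.25)
    }))
  }
  expect_equal(pwm_score("ACT", pwm), hand(c(1, 2, 4)), tolerance = 1e-12)
  expect_error(pwm_score("AC", pwm), "width")
  expect_error(pwm_score("AXT", pwm), "bases")
})

test_that("best-placement scan matches exhaustive enumeration", {
  set.seed(67)
  seq60 <- random_dna(60)
  pwm <- random_pwm(7)
  best <- scan_best(seq60, pwm)
  expect_equal(best$score, scan_oracle(seq60, pwm), tolerance = 1e-10)

  cons <- pwm_consensus(pwm)
  hit <- scan_best(cons, pwm)
  expect_equal(hit$offset, 1)
  expect_equal(hit$strand, "+")

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  embedded <- paste0("CCCCCCCC", rc, "CCCCCCCC")
  # make sure the forward strand can't tie by accident for this PWM
  hit2 <- scan_best(embedded, pwm)
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$offset, 9)
  expect_error(scan_best("ACG", pwm), "shorter")
})

test_that("PWM scores are strand-consistent", {
  set.seed(71)
  for (i in 1:20) {
    pwm <- random_pwm(sample(5:9, 1))
    win <- random_dna(pwm$width)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(win)))
    expect_equal(pwm_score(win, pwm),
                 pwm_score(rc, pwm_reverse_complement(pwm)),
                 tolerance = 1e-10)
  }
})

test_that("allele delta detects the planted motif disruption", {
  sim <- small_sim(seed = 73)
  mo <- sim$motif
  ad <- allele_delta(mo$flank, mo$placement$variant_offset,
                     mo$placement$ref, mo$placement$alt, mo$pwm)
  expect_gt(ad$delta, 0)   # ref allele binds stronger
  expect_true(ad$disrupted)

  same <- allele_delta(mo$flank, mo$placement$variant_offset,
                       mo$placement$ref, mo$placement$ref, mo$pwm)
  expect_equal(same$delta, 0)

  # delta equals the difference of exhaustive full-sequence best scores
  # when overlap is not required
  free <- allele_delta(mo$flank, mo$placement$variant_offset,
                       mo$placement$ref, mo$placement$alt, mo$pwm,
                       require_overlap = FALSE)
  seqs <- apply_allele(mo$flank, mo$placement$variant_offset,
                       mo$placement$ref, mo$placement$alt)
  expect_equal(free$delta,
               scan_oracle(seqs$ref_seq, mo$pwm) -
                 scan_oracle(seqs$alt_seq, mo$pwm),
               tolerance = 1e-10)
})

test_that("PFM files round-trip counts and scoring convention", {
  pwm <- random_pwm(6)
  f <- withr::local_tempfile(fileext = ".pfm")
  write_pfm(pwm, f, name = "test_motif")
  back <- read_pfm(f)
  expect_equal(back$counts, pwm$counts)
  expect_equal(back$probs, pwm$probs)
})
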