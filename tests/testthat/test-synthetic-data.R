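test_that("genotype generator respects Hardy-Weinberg allele frequencies", {
  cfg <- sim_config(n_patients = 1000, n_snps = 5, maf_range = c(0.3, 0.3),
                    seed = 3)
  gt <- simulate_genotypes(cfg)
  arr <- array_variants(gt$geno)
  freqs <- rowMeans(arr$dosages) / 2
  # 2n = 2000 Bernoulli(0.3) draws per SNP; binomial 99.9% CI half-width
  # ~3.3 * sqrt(0.3 * 0.7 / 2000) = 0.034
  expect_true(all(abs(freqs - 0.3) < 0.034))
  expect_true(all(arr$dosages %in% 0:2))
})

test_that("symmetric MAF gives expected dosage near 1", {
  cfg <- sim_config(n_patients = 2000, n_snps = 4, maf_range = c(0.5, 0.5),
                    seed = 5)
  gt <- simulate_genotypes(cfg)
  expect_true(all(abs(rowMeans(array_variants(gt$geno)$dosages) - 1) < 0.08))
})

test_that("planted tag and indel variant are in perfect LD", {
  gt <- simulate_genotypes(sim_config(seed = 9))
  d <- gt$geno$dosages
  expect_identical(d[gt$truth$tag_snp_id, ], d[gt$truth$motif_snp_id, ])
  mv <- gt$geno$variants[gt$geno$variants$id == gt$truth$motif_snp_id, ]
  expect_gt(nchar(mv$alt), nchar(mv$ref))  # insertion allele
  expect_false(mv$on_array)
  expect_true(all(diff(gt$geno$variants$pos) > 0))
})

test_that("degenerate configs are rejected", {
  expect_error(sim_config(n_patients = 1), "n_patients")
  expect_error(sim_config(frac_active = 0), "frac_active")
  expect_error(sim_config(frac_active = 1), "frac_active")
  expect_error(sim_config(maf_range = c(0, 0.3)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_genes = 0), "counts")
})

test_that("activity generator hits the configured active count and valid betas", {
  cfg <- sim_config(n_patients = 366, frac_active = 159 / 366, seed = 21)
  ao <- simulate_activity_omics(cfg)
  expect_equal(sum(ao$labels), 159)
  expect_true(all(ao$cohort$methylation >= 0 & ao$cohort$methylation <= 1))
  # criteria overlap but are not identical: some patients pass 1-2 only
  part <- call_activity(ao$cohort, cfg$regulator_id)
  n_criteria <- part$expr_high + part$cnv_amp + part$hypometh
  expect_gt(sum(n_criteria %in% 1:2), 0)
})

test_that("zero active fraction limit yields almost no called actives", {
  # frac_active must be interior, so emulate the limit with a tiny fraction
  cfg <- sim_config(n_patients = 400, frac_active = 1e-6, seed = 2)
  ao <- simulate_activity_omics(cfg)
  expect_equal(sum(ao$labels), 0)
  part <- call_activity(ao$cohort, cfg$regulator_id)
  # criteria are noisy readouts, so a small tail of inactive patients can
  # pass all three; without true actives that tail stays below 5%
  expect_lt(mean(part$active), 0.05)
})

test_that("noiseless conditional effect gives an exact in-group slope", {
  cfg <- sim_config(n_patients = 80, n_snps = 6, n_genes = 4,
                    noise_sd = 1e-12, effect_beta = 1, seed = 4)
  gt <- simulate_genotypes(cfg)
  ao <- simulate_activity_omics(cfg)
  expr <- simulate_expression(gt$geno, ao$labels, gt$truth, cfg)
  act <- names(ao$labels)[ao$labels]
  fit <- fit_additive(gt$geno$dosages[gt$truth$tag_snp_id, act],
                      expr[gt$truth$target_gene_id, act])
  expect_equal(fit$beta, 1, tolerance = 1e-6)
})

test_that("null effect leaves per-group slopes near zero", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- sim_config(n_patients = 200, n_snps = 6, n_genes = 4,
                      effect_beta = 0, seed = 100 + s)
    gt <- simulate_genotypes(cfg)
    ao <- simulate_activity_omics(cfg)
    expr <- simulate_expression(gt$geno, ao$labels, gt$truth, cfg)
    act <- names(ao$labels)[ao$labels]
    fit <- fit_additive(gt$geno$dosages[gt$truth$tag_snp_id, act],
                        expr[gt$truth$target_gene_id, act])
    se <- fit$beta / fit$t_stat
    if (abs(fit$beta) < 3 * abs(se)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)  # |slope| < 3 SE in >= 95% of seeds
})

test_that("expression generator rejects misaligned patients", {
  cfg <- sim_config(n_patients = 50, seed = 6)
  gt <- simulate_genotypes(cfg)
  ao <- simulate_activity_omics(cfg)
  bad <- ao$labels
  names(bad)[1] <- "someone_else"
  expect_error(simulate_expression(gt$geno, bad, gt$truth, cfg),
               "misaligned")
})

test_that("knockdown generator plants a recoverable downregulated target", {
  cfg <- sim_config(seed = 8)
  truth <- simulate_genotypes(cfg)$truth
  kd <- simulate_knockdown(truth, cfg)
  de <- downregulated_genes(kd)
  expect_true(truth$target_gene_id %in% de$gene_id)
  cd <- combined_difference(kd)
  nulls <- setdiff(names(cd), truth$target_gene_id)
  expect_lt(abs(mean(cd[nulls])), 0.3)  # null genes centered at 0
})

test_that("motif generator emits a 59 nt flank whose ref allele scores higher", {
  cfg <- sim_config(seed = 10)
  gt <- simulate_genotypes(cfg)
  mo <- simulate_sequence_and_pwm(gt$truth, cfg, gt$geno)
  expect_equal(nchar(mo$flank), 59)
  expect_true(mo$pwm$width >= 6 && mo$pwm$width <= 12)
  ad <- allele_delta(mo$flank, mo$placement$variant_offset,
                     mo$placement$ref, mo$placement$alt, mo$pwm)
  expect_gt(ad$delta, 0)
  # consensus achieves the PWM maximum by definition
  cons <- pwm_consensus(mo$pwm)
  expect_equal(pwm_score(cons, mo$pwm), scan_best(cons, mo$pwm)$score)
})

test_that("interval generator tiles disjoint TADs containing the planted pair", {
  cfg <- sim_config(seed = 12)
  gt <- simulate_genotypes(cfg)
  genes <- simulate_genes(cfg, gt$truth, gt$geno)
  iv <- simulate_intervals(gt$truth, cfg, gt$geno, genes)
  td <- iv$tads$intervals
  expect_true(all(diff(td$start) > 0))
  expect_true(all(td$start[-1] >= td$end[-nrow(td)]))
  tag <- gt$geno$variants[gt$geno$variants$id == gt$truth$tag_snp_id, ]
  tss <- genes$tss[genes$gene_id == gt$truth$target_gene_id]
  st <- same_tad(iv$tads, c(tag$chrom, tag$pos - 1), c(tag$chrom, tss - 1))
  expect_true(st$same_tad)
  expect_equal(st$tad_a, gt$truth$tad_id)
})

test_that("identical configs reproduce bit-identical cohorts", {
  a <- simulate_cohort(sim_config(n_patients = 60, n_snps = 8, n_genes = 5,
                                  seed = 33))
  b <- simulate_cohort(sim_config(n_patients = 60, n_snps = 8, n_genes = 5,
                                  seed = 33))
  expect_identical(a, b)
})

test_that("written fixtures round-trip through their formats", {
  sim <- small_sim(seed = 44)
  d <- withr::local_tempdir()
  paths <- write_sim_fixtures(sim, d)

  geno2 <- read_genotype_vcf(paths$vcf)
  expect_identical(unname(geno2$dosages),
                   unname(matrix(as.integer(sim$geno$dosages),
                                 nrow = nrow(sim$geno$dosages))))
  expect_equal(geno2$variants, sim$geno$variants)
  expect_identical(geno2$patient_ids, sim$geno$patient_ids)

  expect_equal(read_matrix_tsv(paths$expression), sim$expression)
  expect_equal(read_bed(paths$tads, disjoint = TRUE)$intervals,
               sim$tads$intervals)
  expect_equal(read_fasta(paths$flank)$sequence, sim$motif$flank)
  pwm2 <- read_pfm(paths$pfm)
  expect_equal(pwm2$counts, sim$motif$pwm$counts,
               ignore_attr = FALSE)
  expect_equal(unclass(read_truth_json(paths$truth))[
    c("tag_snp_id", "motif_snp_id", "target_gene_id")],
    unclass(sim$truth)[c("tag_snp_id", "motif_snp_id", "target_gene_id")])
})

test_that("phased VCF writing keeps haplotype pairs consistent with dosage", {
  cfg <- sim_config(n_patients = 10, n_snps = 4, seed = 55)
  gt <- simulate_genotypes(cfg)
  # construct haplotypes consistent with the dosages
  v <- gt$geno$variants$id
  hap <- matrix(0L, nrow = 2 * 10, ncol = length(v),
                dimnames = list(NULL, v))
  for (s in v) {
    d <- gt$geno$dosages[s, ]
    hap[seq(1, 20, 2), s] <- as.integer(d >= 1)
    hap[seq(2, 20, 2), s] <- as.integer(d == 2)
  }
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gt$geno, f, haplotypes = hap, phased = TRUE)
  lines <- readLines(f)
  expect_true(any(grepl("\\|", lines)))
  geno2 <- read_genotype_vcf(f)
  expect_identical(unname(geno2$dosages[v, ]),
                   unname(matrix(as.integer(gt$geno$dosages[v, ]),
                                 nrow = length(v))))
})
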