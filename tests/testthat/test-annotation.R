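two_tads <- interval_set(
  data.frame(chrom = "chr1", start = c(100, 200), end = c(200, 300),
             name = c("tadA", "tadB")), disjoint = TRUE
)

test_that("TAD membership uses half-open intervals and is symmetric", {
  expect_true(same_tad(two_tads, c("chr1", 120), c("chr1", 180))$same_tad)
  expect_false(same_tad(two_tads, c("chr1", 120), c("chr1", 250))$same_tad)
  # a boundary point belongs to the interval whose half-open range holds it
  at_boundary <- same_tad(two_tads, c("chr1", 200), c("chr1", 250))
  expect_true(at_boundary$same_tad)
  expect_equal(at_boundary$tad_a, "tadB")
  # symmetry
  expect_equal(same_tad(two_tads, c("chr1", 120), c("chr1", 250))$same_tad,
               same_tad(two_tads, c("chr1", 250), c("chr1", 120))$same_tad)
  # unassigned points are FALSE with NA annotation, not an error
  outside <- same_tad(two_tads, c("chr1", 50), c("chr1", 120))
  expect_false(outside$same_tad)
  expect_true(is.na(outside$tad_a))
})

test_that("overlapping TAD sets are rejected, unsorted input is sorted", {
  expect_error(interval_set(
    data.frame(chrom = "chr1", start = c(100, 150), end = c(200, 250),
               name = c("a", "b")), disjoint = TRUE), "overlap")
  expect_error(interval_set(
    data.frame(chrom = "chr1", start = 10, end = 10, name = "x")),
    "start < end")
  shuffled <- interval_set(
    data.frame(chrom = "chr1", start = c(300, 100), end = c(400, 200),
               name = c("b", "a")))
  expect_equal(shuffled$intervals$name, c("a", "b"))
  plain <- interval_set(
    data.frame(chrom = "chr1", start = c(100, 200), end = c(200, 300),
               name = c("a", "b")))
  expect_error(same_tad(plain, c("chr1", 1), c("chr1", 2)), "disjoint")
})

test_that("promoter overlap is strand-aware and order-invariant", {
  peaks <- interval_set(data.frame(
    chrom = "chr1",
    start = c(9500, 20000, 8000),
    end = c(10500, 21000, 8300),
    name = c("span_tss", "far_downstream", "upstream_plus")
  ))
  plus <- promoter_overlap(peaks, list("chr1", 10000, "+"))
  expect_true("span_tss" %in% plus$name)
  expect_true("upstream_plus" %in% plus$name)   # within 2 kb upstream
  expect_false("far_downstream" %in% plus$name) # 10 kb downstream

  # minus strand: upstream extends to higher coordinates
  minus_peaks <- interval_set(data.frame(
    chrom = "chr1", start = c(11500, 8000), end = c(11900, 8300),
    name = c("upstream_minus", "too_far_minus")
  ))
  minus <- promoter_overlap(minus_peaks, list("chr1", 10000, "-"))
  expect_equal(minus$name, "upstream_minus")

  # input order does not matter
  rev_peaks <- interval_set(peaks$intervals[c(3, 1, 2), ])
  expect_equal(promoter_overlap(rev_peaks, list("chr1", 10000, "+")),
               plus)
  expect_error(promoter_overlap(peaks, list("chr1", 10000, "*")), "strand")
})

test_that("minor allele frequency is cohort-anchored and ties go to alt", {
  dos <- matrix(c(0L, 1L, 2L), nrow = 1,
                dimnames = list("s1", paste0("P", 1:3)))
  geno <- genotype_matrix(
    dos, data.frame(id = "s1", chrom = "chr1", pos = 100, ref = "A",
                    alt = "G"), paste0("P", 1:3))
  grp <- setNames(rep("all", 3), paste0("P", 1:3))
  res <- maf_by_group(geno, "s1", grp)
  expect_equal(res$maf, 0.5)
  expect_equal(attr(res, "minor_allele"), "alt")

  dos0 <- matrix(0L, nrow = 1, ncol = 3,
                 dimnames = list("s1", paste0("P", 1:3)))
  geno0 <- genotype_matrix(
    dos0, data.frame(id = "s1", chrom = "chr1", pos = 100, ref = "A",
                     alt = "G"), paste0("P", 1:3))
  expect_equal(maf_by_group(geno0, "s1", grp)$maf, 0)
})

test_that("pooled per-group MAF equals the cohort MAF", {
  sim <- small_sim(seed = 83)
  race <- setNames(sim$clinical$race, sim$clinical$patient_id)
  res <- maf_by_group(sim$geno, sim$truth$tag_snp_id, race)
  pooled <- sum(res$maf * 2 * res$n_patients) / (2 * sum(res$n_patients))
  dose <- sim$geno$dosages[sim$truth$tag_snp_id, ]
  cohort_alt <- mean(dose) / 2
  cohort_maf <- min(cohort_alt, 1 - cohort_alt)
  expect_equal(pooled, cohort_maf, tolerance = 1e-12)
})

test_that("group MAF of planted genotypes matches the generator parameter", {
  cfg <- sim_config(n_patients = 1000, seed = 84)
  gt <- simulate_genotypes(cfg)
  grp <- setNames(rep(c("g1", "g2"), length.out = 1000),
                  gt$geno$patient_ids)
  res <- maf_by_group(gt$geno, gt$truth$tag_snp_id, grp)
  # planted MAF = 0.3; 99.9% binomial CI half-width at n = 1000 is ~0.048
  expect_true(all(abs(res$maf - 0.3) < 0.05))
})

test_that("genotype-feature association matches the hand chi-square", {
  clin <- data.frame(
    carrier = rep(c(FALSE, TRUE), times = c(30, 30)),
    side = rep(c("left", "right", "left", "right"),
               times = c(10, 20, 20, 10)),
    stringsAsFactors = FALSE
  )
  res <- genotype_feature_association(clin, "side")
  # expected counts all 15; chi2 = 4 * (5^2 / 15) = 6.667
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(res$p_value, pchisq(20 / 3, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$method, "chisq")
})

test_that("independence by construction gives chi-square zero", {
  clin <- data.frame(
    carrier = rep(c(FALSE, TRUE), times = c(40, 20)),
    side = c(rep(c("left", "right"), times = c(20, 20)),
             rep(c("left", "right"), times = c(10, 10))),
    stringsAsFactors = FALSE
  )
  res <- genotype_feature_association(clin, "side")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
})

test_that("sparse 2x2 tables fall back to Fisher's exact test", {
  clin <- data.frame(
    carrier = rep(c(FALSE, TRUE), times = c(30, 4)),
    side = c(rep(c("left", "right"), times = c(15, 15)),
             rep("right", 4)),
    stringsAsFactors = FALSE
  )
  res <- genotype_feature_association(clin, "side")
  expect_equal(res$method, "fisher")
  expect_true(res$low_expected)
  expect_error(genotype_feature_association(
    data.frame(carrier = c(TRUE, FALSE), side = c("left", "left")),
    "side"), "single level")
})

test_that("chi-square scales linearly when a table is scaled", {
  base <- data.frame(
    carrier = rep(c(FALSE, TRUE), times = c(30, 30)),
    side = rep(c("left", "right", "left", "right"),
               times = c(10, 20, 20, 10)),
    stringsAsFactors = FALSE
  )
  tripled <- base[rep(seq_len(nrow(base)), 3), ]
  r1 <- genotype_feature_association(base, "side")
  r3 <- genotype_feature_association(tripled, "side")
  expect_equal(r3$statistic, 3 * r1$statistic, tolerance = 1e-10)
})

test_that("clinical summaries report age and stage comparisons", {
  sim <- small_sim(seed = 85)
  cs <- clinical_summaries(sim$clinical)
  expect_true(is.numeric(cs$age_t_test_p))
  expect_named(cs$age_summary, c("FALSE", "TRUE"))
})
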