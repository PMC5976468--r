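# condqtl — condition-specific cis-eQTL discovery

`condqtl` finds cis SNP–gene associations that exist only in the subgroup
of patients where a master transcriptional regulator is active, and then
assembles a mechanistic case for each hit. It is aimed at cancer-genomics
analysts working with cohorts in which a transcription factor is
recurrently amplified (e.g. a squamous-cell carcinoma cohort with an
amplified stem-cell factor): if a regulatory variant sits in one of the
factor's binding sites, its effect on a target gene should appear only
when the factor is abundant, and a whole-cohort eQTL scan will dilute it.

## The method

1. **Stratify.** A patient is regulator-*active* iff all three hold:
   log2 expression of the regulator > cohort mean; copy-number segment
   mean > 0.5; mean promoter-CpG methylation β ≤ 0.4.
2. **Scan per group.** For every SNP within 1 Mb of a gene TSS, fit the
   additive model *y* = α + β·*g* + ε (dosage *g* ∈ {0,1,2}; two-sided
   t-test on β, *n*−2 df), separately in active and inactive patients.
   Benjamini–Hochberg FDR is computed over **all** tested pairs per group;
   a pair is *unique to active* when FDR < 0.01 in the active group only.
3. **Knockdown filter.** Keep pairs whose gene is downregulated upon
   siRNA knockdown of the regulator: after per-sample centering, the sum
   over cell lines of (control − siRNA) must exceed 1.0.
4. **LD + motif.** Expand each surviving SNP to strong-LD partners
   (r² > 0.8 within 250 kb; two-locus EM haplotype frequencies from
   unphased genotypes, D′ and r² from the classical decomposition) and
   score allele-specific motif disruption with a PWM: Δ = best log2-odds
   score of the ref-allele flank − best score of the alt-allele flank,
   rescanning the full spliced sequence so indel alleles are handled
   correctly.
5. **Annotate.** Same-TAD membership of variant and gene TSS (0-based
   half-open intervals), regulator ChIP peaks in the strand-aware
   promoter window (−2000/+500 bp), minor-allele frequency by patient
   subgroup, and carrier-vs-clinical-feature association (chi-square,
   Fisher fallback for sparse 2×2 tables).

A synthetic-data module (`simulate_cohort()`) generates cohorts with a
*planted* regulator-conditional eQTL — a tag SNP in perfect LD with an
off-array motif-disrupting insertion, a knockdown-responsive target gene,
and a shared TAD — so the entire pipeline can be exercised, calibrated,
and power-checked without any external data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
cohort. From the repository root:

```sh
Rscript analysis/01_simulate.R 42      # writes results/sim/
Rscript analysis/02_stratify.R
Rscript analysis/03_eqtl_scan.R
Rscript analysis/04_knockdown_filter.R
Rscript analysis/05_ld_motif.R
Rscript analysis/06_annotate_report.R
```

With seed 42 this prints, among other things:

```
activity_partition: 135 active / 165 inactive of 300 patients
thresholds: expr > 11.05805, cnv > 0.5, beta <= 0.4 (mean)

Tested 225 cis pairs per group; reported 10 active / 13 inactive at p < 0.05
At FDR < 0.01: 1 unique to active, 0 unique to inactive, 0 shared
   snp_id gene_id      beta      p_value          fdr
1 snp0015 GENE001 0.6447426 3.672209e-07 8.262471e-05

1 genes downregulated by the knockdown:
  gene_id combined_diff
1 GENE001      1.794254

snp0015 -> 1 strong-LD partner(s)
  indel0001 T>TA motif scores ref 14.06 / alt 1.96 (delta 12.10)
```

Reading this: of 300 simulated patients, 135 are called regulator-active
(the generator planted 150; stratification is intentionally noisy). The
per-group scans test 225 candidate cis pairs each; exactly one pair —
the planted tag SNP `snp0015` against the planted target `GENE001` —
is significant at FDR < 0.01 in the active group only, with slope 0.64
expression units per alt allele (0.8 was planted; attenuation comes from
the mis-stratified patients). The target gene's combined knockdown
difference 1.79 clears the 1.0 cutoff. LD expansion rediscovers the
off-array insertion `indel0001` at r² = 1, whose reference allele
completes the regulator's binding motif (log2-odds 14.06) while the
insertion disrupts it (1.96): the reference allele binds stronger, so the
variant is a plausible mechanistic cause. The final report
(`results/candidate_report.tsv`) additionally records that variant and
gene share a TAD, that a regulator ChIP peak sits in the target promoter,
and a carrier-vs-tumor-laterality chi-square p-value.

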