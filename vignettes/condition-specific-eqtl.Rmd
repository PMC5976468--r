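---
title: "Condition-specific cis-eQTL discovery: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-specific cis-eQTL discovery: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condqtl)
```

## The scientific problem

A master transcriptional regulator — a transcription factor that is
amplified and overexpressed in a subset of tumors — can create genotype ×
condition interactions: a regulatory variant inside one of the factor's
binding sites only matters in patients where the factor is abundant. A
conventional cis-eQTL scan over the whole cohort dilutes such signals.
`condqtl` implements the alternative: stratify the cohort by the
regulator's activity first, scan each subgroup separately, and keep the
associations that are significant only in the regulator-active group. It
then asks whether a mechanistic account exists for each surviving pair:
does the gene respond to knockdown of the regulator; is the eQTL SNP (or a
strong-LD partner) inside the regulator's binding motif with an
allele-dependent score; do variant and gene share a topologically
associating domain (TAD); does a regulator ChIP peak sit in the gene's
promoter.

## Stratification model

A patient is called regulator-active when all three omic criteria hold
simultaneously:

1. regulator expression strictly above the cohort mean of the regulator's
   log2 expression (the threshold is data-derived, not fixed);
2. copy-number segment mean at the regulator locus strictly above 0.5
   (log-ratio units, i.e. amplification);
3. mean beta-value across the regulator's promoter CpGs at most 0.4
   (hypomethylation; beta in [0, 1]).

Boundary handling follows the inequalities exactly as stated: `>` for
expression and copy number, `<=` for methylation. The promoter methylation
summary is the unweighted mean across the supplied promoter CpGs; no
canonical aggregation rule exists, so `median` and an all-CpGs-pass
variant (`max`) are available through `promoter_methylation()`. The
partition is exhaustive and two-way: every patient not meeting all three
criteria is inactive. On cohorts of the reference kind, roughly 40–50 % of
patients are active; a minority of patients satisfy only one or two
criteria, which is exactly what the correlated-but-noisy criterion model
below generates.

## Association model

For each candidate cis pair (SNP within 1 Mb of a gene's TSS, same
chromosome), the additive model regresses expression on allele dosage
(0/1/2 copies of the alt allele) with an intercept, per patient group:

$$y_i = \alpha + \beta g_i + \varepsilon_i, \qquad
  H_0: \beta = 0 \text{ (two-sided t-test, } n - 2 \text{ df)}$$

`fit_additive()` computes this in closed form; `fit_anova()` offers the
genotype-class complement (one-way ANOVA over the dosage classes, plus
pairwise t-tests, since "ANOVA" is sometimes used loosely for those).
Within each group, p-values are adjusted by Benjamini–Hochberg over **all
tested pairs in that group**. The raw-p output threshold (default 0.05)
only limits what is reported; it never shrinks the multiple-testing
denominator. This matters: an FDR computed over a significance-filtered
subset would be anti-conservative. A pair is *unique to the active group*
when its FDR is below 0.01 in the active scan and not below 0.01 in the
inactive scan; the same FDR rule is applied on both sides because a
raw-p-on-one-side rule is ambiguous (the choice is configurable in
`compare_groups()`).

Monomorphic-in-group SNPs are skipped per group with a logged reason —
they may still be tested in the other group. Missing dosages are dropped
pairwise per (SNP, gene) fit. No covariates enter the default model; a
residualize-then-scan hook can be layered on top of the matrices before
calling `scan_group()` if population structure is a concern (out of scope
here).

## Knockdown filter

The regulator-knockdown experiment is two cell lines, each with one
control and one siRNA profile. Samples are first centered to mean zero
(per-sample location normalization; median optional), then each gene's
evidence is the **sum** over cell lines of (control − siRNA). A gene is
downregulated when that combined difference strictly exceeds 1.0. "Sum"
was chosen over "mean" or "both lines exceed" because a combined value
with a single 1.0 cutoff most plausibly denotes aggregation across the two
lines; the alternatives remain selectable. When several probes map to one
gene the gene takes the maximum combined difference and appears once.
This is a fixed-cutoff filter, not a statistical test — with only one
profile per condition per line there are no within-group degrees of
freedom, so the package deliberately does not attach p-values to it.

## LD and motif disruption

Pairwise LD uses the classical decomposition: `D = p_AB − p_A p_B`,
`D′ = D / D_max` with the sign-dependent bound, `r² = D² / (p_A(1−p_A)
p_B(1−p_B))`. From phased haplotypes these are direct counts; from
unphased genotypes the four two-locus haplotype frequencies come from an
EM algorithm in which only double heterozygotes are phase-ambiguous. EM
starts at linkage equilibrium (products of allele frequencies) — a fixed,
deterministic initialization that resolves the symmetric
all-double-heterozygote likelihood toward D = 0, in which case the result
carries an ambiguity warning. Convergence is declared when the maximum
frequency change drops below 1e-8 (cap 1000 iterations, warning on
non-convergence); the log-likelihood trace is returned so monotone ascent
can be asserted. Strong-LD partners are searched within 250 kb at
r² > 0.8, the conventional strong-LD rule.

Motif disruption is scored with a position weight matrix as summed log2
odds against the background after pseudocount regularization (total
pseudocount 0.8 split by background frequencies — a common motif-library
convention; score scales differ between tools, so absolute scores are
comparable only within this package). For each allele the best placement
over all offsets and both strands is found by exhaustive scan, and
`delta = best_ref − best_alt`. Length-changing alleles (indels) are
handled by splicing the alt allele into the flank and **rescanning the
entire substituted sequence** — an insertion shifts every downstream
placement, so per-position score lookups would be wrong. By default only
placements whose window covers the variant are eligible
(`require_overlap = TRUE`): a reported motif change must involve a window
the variant can actually disrupt.

## Genomic and clinical annotation

Intervals are 0-based half-open internally (the BED convention); VCF and
annotation positions (1-based) are converted once at ingest. A point on a
TAD boundary belongs to the downstream interval, the unambiguous
consequence of half-open ranges. A gene is assigned to a TAD by its TSS
point — a single-point rule with no partial-overlap ambiguity (full-body
overlap can be composed from the interval utilities if wanted). The
promoter window is strand-aware: 2000 bp upstream and 500 bp downstream of
the TSS. Minor-allele frequency per patient category anchors the minor
allele on the whole cohort (tie broken to alt) so per-group frequencies
are comparable. The genotype–clinical association dichotomizes carriers
(≥ 1 minor allele, dominant coding) and uses Pearson's chi-square without
continuity correction, falling back to Fisher's exact test for sparse
2 × 2 tables (any expected count < 5); age is compared by two-sample
t-test and stage by chi-square, as descriptive summaries.

## What the synthetic-data generator emulates

The generator's defaults are the package's reference study conditions: 300
patients, half truly regulator-active, 30 array SNPs and 15 genes on a
3 Mb chromosome, per-SNP MAF uniform in (0.2, 0.4) with the planted tag
SNP at 0.3, and a conditional effect of 0.8 residual standard deviations
per alt allele present only in active patients (`noise_sd = 1`). Those
sizes give the planted pair a within-active-group t-statistic around 6,
comfortable power at FDR < 0.01 over ~250 tested cis pairs, while staying
small enough that the full test suite and calibration runs complete in
well under a minute each.

Layer by layer:

* **Genotypes** are Hardy–Weinberg draws (dosage ~ Binomial(2, MAF)), no
  missingness by default. One off-array insertion variant (T → TA) is
  planted 1.2 kb from the tag SNP with an elementwise-identical dosage
  vector — perfect LD, r² = 1 — mimicking an indel that a genotyping
  array does not carry and that is only reachable through LD. The scan
  therefore runs on array variants only (`array_variants()`), and the LD
  stage rediscovers the indel.
* **Activity criteria** are noisy readouts of a shared latent score
  (true label + N(0, 0.25)): expression 10 + 2.2z + N(0, 0.35), segment
  mean z + N(0, 0.15), promoter beta 0.55 − 0.3z with patient- and
  CpG-level noise, clamped to [0, 1]. Sharing z correlates the criteria;
  the independent noise makes each individually imperfect, reproducing
  the partial-overlap structure of real regulator-amplified cohorts
  (about 95 % stratification agreement with truth at the defaults).
* **Expression** adds the conditional genotype effect and a 0.5-unit mean
  shift on the target gene in active patients (the regulator upregulates
  its target); all other genes are pure noise.
* **Knockdown** plants a 0.9-unit per-line control-minus-siRNA drop on
  the target gene (combined ≈ 1.8, clearing the 1.0 cutoff) and nothing
  on null genes; sample-level offsets ensure the centering step is
  actually exercised.
* **Motif** fixtures embed an 8-bp AT-rich consensus (HMG-box-like) in a
  59 nt flank (±29 around the variant) such that the reference base
  completes the motif and the insertion disrupts every overlapping
  placement. The PWM has 85:5:5:5 column counts, so the planted delta is
  large and sign-stable.
* **TADs** tile the chromosome with boundaries forbidden between the
  planted variant and the target TSS; one ChIP peak is placed inside the
  target promoter plus decoys elsewhere.
* **Clinical** tables plant a carrier-laterality association (right-lung
  predominance among carriers) and race-dependent carrier rates; stage
  and age are independent of genotype.

Every generator owns a seed stream derived deterministically from the one
config seed, so identical configs give bit-identical cohorts regardless
of call order, and the null-calibration generator (`null_pvalues()`)
produces mutually independent SNP–gene pairs whose p-values are exactly
Uniform(0, 1) under the Gaussian model.

What the generator does **not** emulate — and therefore what passing
tests do not certify about real data: realistic LD block structure beyond
the single planted perfect-LD pair; population structure and relatedness;
expression heteroskedasticity, batch effects and hidden confounders;
copy-number-driven expression dosage on the target gene; probe-level
array artifacts in the knockdown data; multi-chromosome genomes. On real
cohorts the scan's calibration depends on assumptions (exchangeable
Gaussian-ish residuals within groups) the generator satisfies by
construction.

## Numerical choices and degenerate inputs

* p-values that underflow to zero in perfect fits are floored at the
  smallest positive double so the BH domain (0, 1] is preserved.
* `bh_fdr()` validates its domain and delegates to the standard step-up
  implementation; tests pin it to a from-definition oracle.
* EM ties (all double heterozygotes) resolve to D = 0 via the
  equilibrium initialization and are flagged, never silently broken.
* `scan_best()` breaks placement ties by smallest offset, forward strand
  first — fixed and documented, so reruns are stable.
* Monomorphic loci are an explicit error in LD (undefined), a logged
  skip in the scan (the pair may be informative in the other group).
* Interval sets declared as TADs are validated non-overlapping at
  construction; overlap is a hard error, not a warning.
* A flank/ref mismatch in `apply_allele()` is a hard error by design: it
  is the cheapest guard against 0/1-based coordinate bugs.

## Problem sizes used in the checks

The calibration and power checks run at deliberately chosen desk-scale
sizes: 5000 independent null pairs for type-I-error calibration (binomial
SE ≈ 0.003 on the 5 % rate, so the 0.05 ± 0.01 band is a ≈ 3-sigma
statement), 50 seeds for conditional-recovery power at the default study
conditions, 500 individuals for EM frequency recovery, and 100 random
instances for each oracle-equivalence check. The end-to-end pipeline
check uses the default 300-patient cohort; because stratification is
itself noisy, per-seed exact recovery sits near 95 %, which is why the
acceptance script reports recovery as a rate over ten independent
pipeline runs rather than a single-seed indicator.

## Known limitations

* The two-group comparison tests "significant here, not there"; it is not
  a formal interaction test, and a pair just under the FDR line in one
  group and just over in the other can flip uniqueness between seeds.
* FDR is controlled within each group separately; no joint control
  across the two scans is attempted.
* LD from unphased genotypes inherits EM's assumptions (random mating,
  no genotyping error); at r² near 1 this is benign, at moderate r² the
  EM estimate has sampling noise of its own.
* PWM deltas are in this package's log2-odds convention; they are not
  numerically comparable to scores from databases using other scales.
* The pipeline evaluates motif disruption only for variants covered by a
  supplied flank sequence; other LD partners are reported with the motif
  fields marked not evaluated.
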