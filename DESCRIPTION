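Package: condqtl
Title: Condition-Specific cis-eQTL Discovery with Regulator-Based Patient Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers cis expression quantitative trait loci (eQTLs) that are
    specific to a patient subgroup defined by the activity of a master
    transcriptional regulator. Patients are partitioned by three omic criteria
    (regulator expression above the cohort mean, copy-number segment mean
    above 0.5, promoter methylation beta at or below 0.4); an additive linear
    cis scan with Benjamini-Hochberg false-discovery control is run per group;
    group-unique pairs are filtered by regulator-knockdown differential
    expression; surviving variants are expanded to strong-LD partners
    (two-locus EM haplotype frequencies from unphased genotypes), scored for
    allele-specific binding-motif disruption with a position weight matrix
    (including length-changing indel alleles), and annotated for shared
    topologically associating domains, promoter ChIP peaks, subgroup minor
    allele frequencies, and genotype-clinical associations. A synthetic-data
    module generates cohorts with planted regulator-conditional eQTLs so the
    whole pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
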