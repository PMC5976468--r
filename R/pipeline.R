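#' Run the full condition-specific eQTL pipeline
#'
#' Executes, in order: activity stratification, per-group cis scan, group
#' comparison (unique-to-active pairs), knockdown-DE filter, strong-LD
#' expansion with motif-disruption scoring, and TAD / promoter-peak /
#' clinical annotation. Deterministic given the config and input files;
#' every stage's input/output counts are recorded in a machine-readable
#' run manifest.
#'
#' @param config Either a path to a YAML config (as written by
#'   [write_sim_fixtures()]) or the equivalent named list with elements
#'   `inputs` (file paths), `regulator`, `thresholds`, `seed`.
#' @return A `pipeline_result`: list(report — one row per surviving
#'   candidate with all evidence layers; comparison — the full group
#'   comparison; partition; manifest — stage counts and thresholds).
#'   Evidence that could not be computed for a candidate is NA, with the
#'   reason in the `notes` column ("not evaluated: ...").
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  th <- utils::modifyList(default_thresholds(),
                          config$thresholds %||% list())
  ins <- config$inputs
  stage <- "input"
  result <- tryCatch({
    geno <- read_genotype_vcf(ins$vcf)
    expr <- read_matrix_tsv(ins$expression)
    genes <- utils::read.table(ins$genes, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    omics <- omics_cohort(
      expression = read_matrix_tsv(ins$omics_expression),
      cnv = read_matrix_tsv(ins$cnv),
      methylation = read_matrix_tsv(ins$methylation),
      promoter_cpgs = readLines(ins$promoter_cpgs),
      patient_ids = colnames(read_matrix_tsv(ins$omics_expression))
    )
    kd <- kd_experiment(
      read_matrix_tsv(ins$knockdown),
      utils::read.table(ins$knockdown_samples, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    )
    tads <- read_bed(ins$tads, disjoint = TRUE)
    peaks <- read_bed(ins$peaks)
    flank <- read_fasta(ins$flank)
    pwm <- read_pfm(ins$pfm)
    placement <- jsonlite::read_json(ins$motif_placement,
                                     simplifyVector = TRUE)
    clinical <- utils::read.table(ins$clinical, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)

    stage <- "stratification"
    part <- call_activity(omics, config$regulator,
                          cnv_threshold = th$cnv, beta_threshold = th$beta)
    active <- part$patient_id[part$active]
    inactive <- part$patient_id[!part$active]
    if (length(active) == 0L || length(inactive) == 0L) {
      stop("stratification produced an empty group")
    }

    stage <- "eqtl_scan"
    arr <- array_variants(geno)
    scan_a <- scan_group(arr, expr, genes, active, group = "active",
                         window_bp = th$cis_window_bp,
                         p_out_threshold = th$p_out)
    scan_i <- scan_group(arr, expr, genes, inactive, group = "inactive",
                         window_bp = th$cis_window_bp,
                         p_out_threshold = th$p_out)
    cmp <- compare_groups(scan_a, scan_i, fdr_threshold = th$fdr)

    stage <- "knockdown_de"
    de <- downregulated_genes(kd, threshold = th$de_diff)
    cand <- filter_pairs_by_de(cmp$unique_to_active, de)

    stage <- "ld_motif_annotation"
    report <- .annotate_candidates(cand, geno, genes, de, tads, peaks,
                                   flank, pwm, placement, clinical, th,
                                   scan_i)

    manifest <- list(
      thresholds = th,
      seed = config$seed,
      package_version = as.character(utils::packageVersion("condqtl")),
      counts = list(
        patients = nrow(part),
        active = length(active),
        inactive = length(inactive),
        cis_pairs_tested_active = attr(scan_a, "n_tested"),
        cis_pairs_tested_inactive = attr(scan_i, "n_tested"),
        reported_active = nrow(scan_a),
        reported_inactive = nrow(scan_i),
        unique_to_active = nrow(cmp$unique_to_active),
        unique_to_inactive = nrow(cmp$unique_to_inactive),
        shared = nrow(cmp$shared),
        de_genes = nrow(de),
        de_filtered_candidates = nrow(cand),
        final_candidates = nrow(report)
      )
    )
    structure(list(report = report, comparison = cmp, partition = part,
                   de_genes = de, manifest = manifest),
              class = "pipeline_result")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.annotate_candidates <- function(cand, geno, genes, de, tads, peaks, flank,
                                 pwm, placement, clinical, th, scan_i) {
  n <- nrow(cand)
  cols <- c("p_inactive", "fdr_inactive", "combined_de_diff", "ld_partner",
            "ld_r2", "ld_dprime", "score_ref", "score_alt", "motif_delta",
            "same_tad", "tad_id", "promoter_peaks", "clinical_location_p",
            "clinical_method", "notes")
  extra <- as.data.frame(matrix(NA, nrow = n, ncol = length(cols),
                                dimnames = list(NULL, cols)))
  extra$notes <- character(n)
  report <- cbind(cand, extra)
  if (n == 0L) return(report)

  key_i <- paste(scan_i$snp_id, scan_i$gene_id)
  for (k in seq_len(n)) {
    snp <- report$snp_id[k]; gene <- report$gene_id[k]
    note <- character(0)

    mi <- match(paste(snp, gene), key_i)
    if (!is.na(mi)) {
      report$p_inactive[k] <- scan_i$p_value[mi]
      report$fdr_inactive[k] <- scan_i$fdr[mi]
    } else {
      note <- c(note, "not evaluated: pair below reporting threshold in inactive group")
    }

    di <- match(gene, de$gene_id)
    report$combined_de_diff[k] <- if (is.na(di)) NA_real_ else
      de$combined_diff[di]

    ld <- strong_ld_partners(geno, snp, r2_threshold = th$r2,
                             window_bp = th$ld_window_bp)
    if (nrow(ld) > 0L) {
      best <- ld[which.max(ld$r2), ]
      report$ld_partner[k] <- best$partner
      report$ld_r2[k] <- best$r2
      report$ld_dprime[k] <- best$D_prime
      pv <- geno$variants[geno$variants$id == best$partner, ]
      if (identical(pv$chrom, as.character(placement$chrom)) &&
          pv$pos >= placement$flank_start &&
          pv$pos < placement$flank_start + nchar(flank$sequence)) {
        off <- pv$pos - placement$flank_start + 1L
        ad <- allele_delta(flank$sequence, off, pv$ref, pv$alt, pwm)
        report$score_ref[k] <- ad$best_ref$score
        report$score_alt[k] <- ad$best_alt$score
        report$motif_delta[k] <- ad$delta
      } else {
        note <- c(note, "not evaluated: no flank sequence for LD partner")
      }
      anchor <- c(pv$chrom, pv$pos - 1L)
    } else {
      note <- c(note, "not evaluated: no strong-LD partner in window")
      sv <- geno$variants[geno$variants$id == snp, ]
      anchor <- c(sv$chrom, sv$pos - 1L)
    }

    gi <- genes[genes$gene_id == gene, ]
    st <- same_tad(tads, anchor, c(gi$chrom, gi$tss - 1L))
    report$same_tad[k] <- st$same_tad
    report$tad_id[k] <- if (isTRUE(st$same_tad)) st$tad_a else NA_character_

    po <- promoter_overlap(peaks, list(gi$chrom, gi$tss - 1L, gi$strand),
                           upstream_bp = th$promoter_upstream_bp,
                           downstream_bp = th$promoter_downstream_bp)
    report$promoter_peaks[k] <- if (nrow(po) > 0L) {
      paste(po$name, collapse = ",")
    } else NA_character_

    clin <- clinical
    clin$carrier <- geno$dosages[snp, clin$patient_id] >= 1L
    assoc <- tryCatch(genotype_feature_association(clin, "laterality"),
                      error = function(e) NULL)
    if (!is.null(assoc)) {
      report$clinical_location_p[k] <- assoc$p_value
      report$clinical_method[k] <- assoc$method
    } else {
      note <- c(note, "not evaluated: laterality has a single level")
    }
    report$notes[k] <- paste(note, collapse = "; ")
  }
  rownames(report) <- NULL
  report
}

#' Write pipeline outputs to disk
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @return list of paths (report TSV, manifest JSON), invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  report_path <- file.path(dir, "candidate_report.tsv")
  manifest_path <- file.path(dir, "run_manifest.json")
  utils::write.table(result$report, report_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(result$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(report = report_path, manifest = manifest_path))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("pipeline_result:", cnt$active, "active /", cnt$inactive,
      "inactive patients;", cnt$unique_to_active, "unique-to-active pairs;",
      cnt$de_filtered_candidates, "after DE filter;",
      cnt$final_candidates, "final candidates\n")
  invisible(x)
}
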