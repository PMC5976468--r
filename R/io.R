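#' Write a genotype matrix to VCF v4.2
#'
#' Emits a minimal VCF with a GT FORMAT field. Unphased genotypes are coded
#' 0/0, 0/1, 1/1 from dosage; with `phased = TRUE` and a haplotype matrix,
#' genotypes are written with the `|` separator. Variants flagged off-array
#' carry `ARRAY=0` in INFO so the flag round-trips.
#'
#' @param geno `genotype_matrix`.
#' @param path Output file.
#' @param haplotypes Optional haplotype x variant binary matrix (2 rows per
#'   patient, column names = variant IDs) for phased output.
#' @param phased Write phased separators (requires `haplotypes`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path, haplotypes = NULL, phased = FALSE) {
  if (phased && is.null(haplotypes)) {
    stop("phased output requires a haplotype matrix")
  }
  v <- geno$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    "##INFO=<ID=ARRAY,Number=1,Type=Integer,Description=\"On genotyping array\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$patient_ids), collapse = "\t")
  ), con)
  sep <- if (phased) "|" else "/"
  for (i in seq_len(nrow(v))) {
    if (phased) {
      h <- haplotypes[, v$id[i]]
      a1 <- h[seq(1, length(h), 2)]
      a2 <- h[seq(2, length(h), 2)]
      gt <- paste(a1, a2, sep = sep)
    } else {
      d <- geno$dosages[v$id[i], ]
      gt <- c("0/0", "0/1", "1/1")[d + 1L]
      gt[is.na(d)] <- "./."
    }
    writeLines(paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i],
                       ".", "PASS", sprintf("ARRAY=%d", as.integer(v$on_array[i])),
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a genotype matrix from VCF
#'
#' Parses GT fields into alt-allele dosages. Multi-allelic records are
#' rejected; missing genotypes become NA. The `ARRAY` INFO flag written by
#' [write_vcf()] is restored into `on_array` (absent flag means TRUE).
#'
#' @param path VCF file.
#' @return A `genotype_matrix`.
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multi-allelic sites are not supported")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    if (is.na(x) || x %in% c("./.", ".|.", ".")) return(NA_integer_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]))
  }
  dos <- apply(gt, c(1, 2), count_alt)
  on_array <- !grepl("ARRAY=0", ifelse(is.na(fix$INFO), "", fix$INFO))
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, on_array = on_array,
                         stringsAsFactors = FALSE)
  rownames(dos) <- variants$id
  genotype_matrix(dos, variants, colnames(gt))
}

#' Write / read a numeric matrix as TSV (rows x patients)
#'
#' Header row holds the column (patient/sample) IDs; first column the row
#' (gene/CpG/locus) IDs.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path File path.
#' @return `path` invisibly / the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read BED3+name interval files
#'
#' BED is consumed natively: starts are 0-based half-open, matching the
#' package's internal convention.
#'
#' @param iset An [interval_set()] (or its data.frame).
#' @param path File path.
#' @param disjoint Validation flag passed to [interval_set()] on read.
#' @return `path` invisibly / an `interval_set`.
#' @export
write_bed <- function(iset, path) {
  df <- if (inherits(iset, "interval_set")) iset$intervals else iset
  utils::write.table(df[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path, disjoint = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name"),
                          stringsAsFactors = FALSE)
  interval_set(df, disjoint = disjoint)
}

#' Write / read a single-sequence FASTA
#'
#' @param sequence Character scalar (DNA).
#' @param name Sequence header.
#' @param path File path.
#' @return `path` invisibly / list(name, sequence).
#' @export
write_fasta <- function(sequence, name, path) {
  x <- Biostrings::DNAStringSet(sequence)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  list(name = names(x)[1], sequence = as.character(x[[1]]))
}

#' Write / read a position frequency matrix as labeled text
#'
#' Four labeled rows (A/C/G/T) of counts, the minimal JASPAR-style layout:
#' `A  [ 10 2 85 ... ]` or plain whitespace-separated `A 10 2 85 ...`.
#'
#' @param pwm A [pwm_matrix()].
#' @param path File path.
#' @param name Motif name written as a `>` header line.
#' @return `path` invisibly / a `pwm` object.
#' @export
write_pfm <- function(pwm, path, name = "motif") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", name), con)
  for (b in c("A", "C", "G", "T")) {
    writeLines(paste(b, "[",
                     paste(format(pwm$counts[b, ], trim = TRUE),
                           collapse = " "), "]"), con)
  }
  invisible(path)
}

#' @rdname write_pfm
#' @export
read_pfm <- function(path, background = rep(0.25, 4), pseudocount = 0.8) {
  lines <- readLines(path)
  lines <- lines[!grepl("^>", lines) & nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    parts <- strsplit(trimws(gsub("[][]", " ", l)), "\\s+")[[1]]
    list(base = parts[1], counts = as.numeric(parts[-1]))
  })
  bases <- vapply(rows, `[[`, character(1), "base")
  if (!setequal(bases, c("A", "C", "G", "T"))) {
    stop("PFM must have exactly the four rows A, C, G, T")
  }
  counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
  rownames(counts) <- bases
  pwm_matrix(counts[c("A", "C", "G", "T"), , drop = FALSE],
             background = background, pseudocount = pseudocount)
}

#' Write / read the planted-truth record as JSON
#'
#' @param truth A `planted_truth`.
#' @param path File path.
#' @return `path` invisibly / a `planted_truth`.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "planted_truth")
}
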