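#' Position weight matrix with background model
#'
#' Builds a PWM object from a 4 x width count (or frequency) matrix in
#' A, C, G, T row order. Scores are log2 odds against the background after
#' pseudocount regularization: each column's probabilities are
#' `(count + pseudocount * background) / (colsum + pseudocount)`, the
#' convention common to motif libraries.
#'
#' @param counts 4 x width numeric matrix, rows A, C, G, T.
#' @param background Length-4 strictly positive frequencies summing to 1.
#' @param pseudocount Total pseudocount split across bases by the background
#'   (default 0.8).
#' @return A `pwm` object with elements `counts`, `probs`, `background`,
#'   `pseudocount`, `width`.
#' @export
pwm_matrix <- function(counts, background = rep(0.25, 4), pseudocount = 0.8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PWM counts must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("PWM counts must be non-negative")
  if (length(background) != 4L || any(background <= 0)) {
    stop("background must be 4 strictly positive frequencies")
  }
  background <- background / sum(background)
  rownames(counts) <- c("A", "C", "G", "T")
  probs <- sweep(counts + pseudocount * background, 2,
                 colSums(counts) + pseudocount, "/")
  structure(list(counts = counts, probs = probs, background = background,
                 pseudocount = pseudocount, width = ncol(counts)),
            class = "pwm")
}

#' Consensus sequence of a PWM
#'
#' @param pwm A [pwm_matrix()].
#' @return Character scalar; per-position ties broken in A, C, G, T order.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$probs)[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Reverse-complement a PWM
#'
#' @param pwm A [pwm_matrix()].
#' @return The PWM scoring the reverse-complement strand (rows swapped
#'   A<->T, C<->G and columns reversed). Background is complement-swapped.
#' @export
pwm_reverse_complement <- function(pwm) {
  idx <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G
  pwm_matrix(pwm$counts[idx, rev(seq_len(pwm$width)), drop = FALSE],
             background = pwm$background[idx],
             pseudocount = pwm$pseudocount)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Log2-odds PWM score of a single window
#'
#' @param window Character scalar of length exactly `pwm$width`, bases in
#'   A, C, G, T, N (case-insensitive). `N` contributes 0 (background odds).
#' @param pwm A [pwm_matrix()].
#' @return Numeric log2-odds score.
#' @export
pwm_score <- function(window, pwm) {
  window <- toupper(window)
  if (nchar(window) != pwm$width) {
    stop("window length (", nchar(window), ") must equal PWM width (",
         pwm$width, ")")
  }
  b <- strsplit(window, "")[[1]]
  if (!all(b %in% c("A", "C", "G", "T", "N"))) {
    stop("window contains bases outside {A, C, G, T, N}")
  }
  s <- 0
  for (j in seq_len(pwm$width)) {
    if (b[j] == "N") next
    i <- match(b[j], c("A", "C", "G", "T"))
    s <- s + log2(unname(pwm$probs[i, j]) / pwm$background[i])
  }
  s
}

#' Best PWM hit over all offsets and both strands
#'
#' Slides the PWM across the sequence; each placement is scored forward and
#' as the reverse complement of the window. Ties are broken by smallest
#' offset, forward strand first.
#'
#' @param sequence Character scalar, length >= PWM width.
#' @param pwm A [pwm_matrix()].
#' @param overlap Optional length-2 integer (1-based inclusive sequence
#'   interval); when given, only placements whose window intersects the
#'   interval are eligible.
#' @return list(score, offset (1-based window start), strand ("+"/"-")).
#' @export
scan_best <- function(sequence, pwm, overlap = NULL) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  w <- pwm$width
  if (L < w) stop("sequence (", L, " nt) shorter than PWM width (", w, ")")
  starts <- seq_len(L - w + 1L)
  if (!is.null(overlap)) {
    starts <- starts[starts <= overlap[2] & (starts + w - 1L) >= overlap[1]]
    if (length(starts) == 0L) stop("no placement overlaps the given interval")
  }
  best <- list(score = -Inf, offset = NA_integer_, strand = NA_character_)
  for (st in starts) {
    win <- substr(sequence, st, st + w - 1L)
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") pwm_score(win, pwm) else
        pwm_score(.revcomp(win), pwm)
      if (sc > best$score) {
        best <- list(score = sc, offset = st, strand = strand)
      }
    }
  }
  best
}

#' Substitute a variant's alleles into a flanking sequence
#'
#' @param flank Character scalar (reference flanking sequence).
#' @param offset 1-based position of the ref allele's first base in `flank`.
#' @param ref,alt Allele strings; `alt` may differ in length (indel).
#' @return list(ref_seq, alt_seq); `ref_seq` is the flank unchanged.
#' @export
apply_allele <- function(flank, offset, ref, alt) {
  flank <- toupper(flank); ref <- toupper(ref); alt <- toupper(alt)
  found <- substr(flank, offset, offset + nchar(ref) - 1L)
  if (found != ref) {
    stop("flank has '", found, "' at offset ", offset,
         " but ref allele is '", ref, "' (coordinate mismatch)")
  }
  alt_seq <- paste0(substr(flank, 1L, offset - 1L), alt,
                    substr(flank, offset + nchar(ref), nchar(flank)))
  list(ref_seq = flank, alt_seq = alt_seq)
}

#' Allele-specific motif disruption score
#'
#' Scores the best PWM hit on the reference and alternate versions of a
#' variant's flanking sequence and reports the difference. Length-changing
#' alleles are handled by rescanning the substituted sequence in full, since
#' an insertion or deletion shifts every downstream placement. With
#' `require_overlap = TRUE` (default) only placements whose window covers
#' the variant site are eligible, so a reported change always involves a
#' motif instance that the variant can disrupt.
#'
#' @param flank Reference flanking sequence.
#' @param offset 1-based position of the ref allele in `flank`.
#' @param ref,alt Allele strings.
#' @param pwm A [pwm_matrix()].
#' @param require_overlap Restrict placements to windows covering the
#'   variant (default TRUE).
#' @param min_delta Minimum |delta| for the `disrupted` flag (default 0, so
#'   any score change is flagged).
#' @return list(best_ref, best_alt, delta = best_ref$score -
#'   best_alt$score, disrupted).
#' @export
allele_delta <- function(flank, offset, ref, alt, pwm,
                         require_overlap = TRUE, min_delta = 0) {
  seqs <- apply_allele(flank, offset, ref, alt)
  ov_ref <- if (require_overlap) {
    c(offset, offset + nchar(ref) - 1L)
  } else NULL
  ov_alt <- if (require_overlap) {
    c(offset, offset + nchar(alt) - 1L)
  } else NULL
  best_ref <- scan_best(seqs$ref_seq, pwm, overlap = ov_ref)
  best_alt <- scan_best(seqs$alt_seq, pwm, overlap = ov_alt)
  delta <- best_ref$score - best_alt$score
  list(best_ref = best_ref, best_alt = best_alt, delta = delta,
       disrupted = abs(delta) >= min_delta)
}
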