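#' @useDynLib gapcircuit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from a count (or frequency) matrix
#'
#' Converts a per-position nucleotide count matrix into a log-odds scoring
#' matrix. Each row is smoothed with a pseudocount, normalized, and divided by
#' the background nucleotide distribution before taking logs, so that the
#' score of a word is the log-likelihood ratio of motif versus background.
#'
#' @param counts numeric matrix with one row per motif position and four
#'   columns in A, C, G, T order. Counts are expected; probability rows are
#'   accepted (they are simply counts summing to one) but then a pseudocount
#'   of the default magnitude smooths them heavily, so pass a smaller
#'   `pseudocount` for frequency input.
#' @param tf_name identifier of the transcription factor.
#' @param background nucleotide background probabilities (A, C, G, T);
#'   must sum to one. Default uniform.
#' @param pseudocount value added to every cell before normalization.
#' @param threshold log-odds cutoff attached to the PWM and used as the
#'   default when scanning. `NULL` defaults to 0 (better than background).
#' @return an object of class `pwm`: list with `tf_name`, `matrix` (log-odds,
#'   positions x ACGT), `background`, `length`, `threshold`, `max_score`
#'   (score of the consensus word) and `consensus`.
#' @export
pwm <- function(counts, tf_name, background = rep(0.25, 4), pseudocount = 1,
                threshold = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L) stop("zero-length PWM matrix")
  if (ncol(counts) != 4L) stop("PWM matrix must have 4 columns (A,C,G,T)")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("PWM counts must be finite and non-negative")
  }
  background <- as.numeric(background)
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0)) {
    stop("background must be 4 positive probabilities summing to 1")
  }
  sm <- counts + pseudocount
  probs <- sm / rowSums(sm)
  lo <- log(sweep(probs, 2L, background, "/"))
  dimnames(lo) <- list(NULL, DNA_BASES)
  cons_idx <- apply(lo, 1L, which.max)
  out <- structure(list(
    tf_name = as.character(tf_name),
    matrix = lo,
    background = background,
    length = nrow(lo),
    threshold = if (is.null(threshold)) 0 else as.numeric(threshold),
    max_score = sum(apply(lo, 1L, max)),
    consensus = paste(DNA_BASES[cons_idx], collapse = "")
  ), class = "pwm")
  out
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s: length %d, consensus %s, max score %.3f, threshold %.3f\n",
              x$tf_name, x$length, x$consensus, x$max_score, x$threshold))
  invisible(x)
}

#' Read a PWM from a plain-text matrix file
#'
#' The format is a `>TFNAME` header line followed by whitespace-delimited
#' rows of four numbers (A, C, G, T counts), one row per motif position.
#'
#' @param path file containing exactly one PWM record.
#' @inheritParams pwm
#' @return a [pwm()] object.
#' @export
read_pwm <- function(path, background = rep(0.25, 4), pseudocount = 1,
                     threshold = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (length(headers) != 1L || headers[1L] != 1L) {
    stop("expected a single '>TFNAME' header on the first line of ", path)
  }
  tf_name <- sub("^>\\s*", "", lines[1L])
  body <- lines[-1L]
  if (length(body) == 0L) stop("zero-length PWM matrix in ", path)
  fields <- strsplit(body, "\\s+")
  if (any(lengths(fields) != 4L)) {
    stop("malformed PWM row (expected 4 columns) in ", path)
  }
  counts <- matrix(as.numeric(unlist(fields)), ncol = 4L, byrow = TRUE)
  if (any(is.na(counts))) stop("non-numeric PWM entry in ", path)
  pwm(counts, tf_name, background = background, pseudocount = pseudocount,
      threshold = threshold)
}

#' Write a PWM count matrix file
#'
#' Writes a `>TFNAME` header plus a 4-column matrix. Because the stored
#' scoring matrix is log-odds, the underlying smoothed probabilities are
#' recovered and written as frequencies.
#'
#' @param x a `pwm` object.
#' @param path output file.
#' @export
write_pwm <- function(x, path) {
  stopifnot(inherits(x, "pwm"))
  probs <- exp(x$matrix) * rep(x$background, each = x$length)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", x$tf_name), con)
  apply(probs, 1L, function(r) writeLines(paste(format(r, digits = 10),
                                                collapse = "\t"), con))
  invisible(path)
}

#' Log-odds score of a word under a PWM
#'
#' Sums the log-odds matrix entries for the observed base at each motif
#' position. Words containing ambiguous (non-ACGT) characters are rejected
#' with a warning and score `NA`.
#'
#' @param pwm a [pwm()] object.
#' @param word nucleotide string of length `pwm$length`.
#' @return numeric score (NA for ambiguous words).
#' @export
llr_score <- function(pwm, word) {
  stopifnot(inherits(pwm, "pwm"))
  chars <- strsplit(toupper(word), "")[[1L]]
  if (length(chars) != pwm$length) {
    stop("word length ", length(chars), " != PWM length ", pwm$length)
  }
  idx <- match(chars, DNA_BASES)
  if (anyNA(idx)) {
    warning("ambiguous base in word '", word, "'; site skipped")
    return(NA_real_)
  }
  sum(pwm$matrix[cbind(seq_len(pwm$length), idx)])
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## score every window of `codes` (integer base codes, NA = ambiguous);
## returns vector of length n - w + 1 with NA where a window is ambiguous
scan_codes <- function(mat, codes) {
  w <- nrow(mat)
  n <- length(codes)
  if (n < w) return(numeric(0))
  np <- n - w + 1L
  sc <- numeric(np)
  for (k in seq_len(w)) {
    b <- codes[k:(k + np - 1L)]
    contrib <- rep(NA_real_, np)
    ok <- !is.na(b)
    contrib[ok] <- mat[k, b[ok]]
    sc <- sc + contrib
  }
  sc
}

#' Predict binding sites for one PWM on a regulatory region
#'
#' Scores every window on both strands and reports those with log-odds score
#' at or above the threshold. Coordinates are 0-based half-open on the
#' forward strand of the region; for minus-strand sites `word` is the
#' reverse complement of the region subsequence, i.e. the word as matched by
#' the PWM.
#'
#' @param pwm a [pwm()] object.
#' @param region a [regulatory_region()] object, or a plain nucleotide string.
#' @param threshold log-odds cutoff; defaults to `pwm$threshold`.
#' @return data.frame of binding sites: `tf`, `start`, `end`, `strand`,
#'   `word`, `llr`, sorted by `start`.
#' @export
scan_sequence <- function(pwm, region, threshold = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  seq <- if (inherits(region, "regulatory_region")) region$sequence else region
  if (!nzchar(seq)) stop("empty sequence")
  if (is.null(threshold)) threshold <- pwm$threshold
  chars <- strsplit(toupper(seq), "")[[1L]]
  n <- length(chars)
  w <- pwm$length

  hit_frame <- function(scores, strand) {
    keep <- which(!is.na(scores) & scores >= threshold)
    if (length(keep) == 0L) return(empty_sites())
    if (strand == "+") {
      start <- keep - 1L
    } else {
      ## window j on the reverse complement covers forward [n-j-w+1, n-j+1)
      start <- n - (keep - 1L) - w
    }
    word <- vapply(keep, function(j) {
      s <- if (strand == "+") j else n - j - w + 2L
      wd <- paste(chars[s:(s + w - 1L)], collapse = "")
      if (strand == "-") reverse_complement(wd) else wd
    }, character(1L))
    data.frame(tf = pwm$tf_name, start = start, end = start + w,
               strand = strand, word = word, llr = scores[keep],
               stringsAsFactors = FALSE)
  }

  codes <- match(chars, DNA_BASES)
  fwd <- hit_frame(scan_codes(pwm$matrix, codes), "+")
  codes_rc <- rev(5L - codes)
  rev <- hit_frame(scan_codes(pwm$matrix, codes_rc), "-")
  out <- rbind(fwd, rev)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_sites <- function() {
  data.frame(tf = character(0), start = integer(0), end = integer(0),
             strand = character(0), word = character(0), llr = numeric(0),
             stringsAsFactors = FALSE)
}

#' Construct a regulatory region
#'
#' A container for one gene's regulatory sequence together with predicted
#' binding sites, DNase accessibility intervals and named cis-regulatory
#' elements (CREs). All coordinates are 0-based half-open on the region.
#'
#' @param gene gene identifier.
#' @param sequence nucleotide string.
#' @param tss_offset 0-based position of the transcription start site within
#'   the region (used for TSS-relative reporting).
#' @param accessibility data.frame with `start`, `end` columns (0-based
#'   half-open), or NULL for "everything accessible".
#' @param cres named list of `c(start, end)` intervals.
#' @param sites optional precomputed site data.frame as from
#'   [scan_sequence()].
#' @return an object of class `regulatory_region`.
#' @export
regulatory_region <- function(gene, sequence, tss_offset = 0L,
                              accessibility = NULL, cres = list(),
                              sites = empty_sites()) {
  sequence <- toupper(as.character(sequence))
  n <- nchar(sequence)
  if (nrow(sites) > 0L && (any(sites$start < 0L) || any(sites$end > n))) {
    stop("sites outside the region sequence")
  }
  structure(list(gene = as.character(gene), sequence = sequence,
                 tss_offset = as.integer(tss_offset),
                 accessibility = accessibility, cres = cres, sites = sites),
            class = "regulatory_region")
}

#' @export
print.regulatory_region <- function(x, ...) {
  cat(sprintf("Regulatory region %s: %d bp, TSS at %d, %d sites, %d CREs\n",
              x$gene, nchar(x$sequence), x$tss_offset, nrow(x$sites),
              length(x$cres)))
  invisible(x)
}

#' Predict and attach binding sites for a set of PWMs
#'
#' Scans the region with each PWM, pools the hits, optionally applies the
#' accessibility filter, and stores the result in `region$sites`.
#'
#' @param region a [regulatory_region()].
#' @param pwms list of [pwm()] objects.
#' @param apply_accessibility if TRUE (default) and the region carries
#'   accessibility intervals, sites not overlapping open chromatin are
#'   dropped.
#' @return the region with `sites` filled in.
#' @export
predict_sites <- function(region, pwms, apply_accessibility = TRUE) {
  stopifnot(inherits(region, "regulatory_region"))
  hits <- do.call(rbind, lapply(pwms, scan_sequence, region = region))
  if (is.null(hits)) hits <- empty_sites()
  hits <- hits[order(hits$start, hits$tf, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  if (apply_accessibility && !is.null(region$accessibility)) {
    hits <- filter_sites_by_accessibility(hits, region$accessibility)
  }
  region$sites <- hits
  region
}

sites_to_iranges <- function(sites) {
  IRanges::IRanges(start = sites$start + 1L, end = sites$end)
}

#' Keep binding sites overlapping open-chromatin intervals
#'
#' A site is retained when it shares at least one base pair with any
#' accessibility interval (half-open interval convention; a site ending
#' where an interval starts does not overlap).
#'
#' @param sites site data.frame as from [scan_sequence()].
#' @param intervals data.frame with `start`, `end` (0-based half-open).
#' @return the retained subset of `sites`.
#' @export
filter_sites_by_accessibility <- function(sites, intervals) {
  if (nrow(sites) == 0L || is.null(intervals) || nrow(intervals) == 0L) {
    return(sites[integer(0), , drop = FALSE])
  }
  ir_sites <- sites_to_iranges(sites)
  ir_int <- IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  keep <- IRanges::countOverlaps(ir_sites, ir_int, minoverlap = 1L) > 0L
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict a region's sites to those overlapping a named CRE
#'
#' Used to emulate reporter constructs: only the binding sites overlapping
#' the cis-regulatory element carried by the construct drive the reporter.
#'
#' @param region a [regulatory_region()] with sites and named CREs.
#' @param cre_name name of an interval in `region$cres`.
#' @return the subset of `region$sites` with >= 1 bp overlap with the CRE.
#' @export
restrict_sites_to_cre <- function(region, cre_name) {
  stopifnot(inherits(region, "regulatory_region"))
  if (!cre_name %in% names(region$cres)) {
    stop("unknown CRE name: ", cre_name)
  }
  cre <- region$cres[[cre_name]]
  filter_sites_by_accessibility(region$sites,
                                data.frame(start = cre[1L], end = cre[2L]))
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Wraps `rtracklayer::import` and returns 0-based half-open coordinates
#' (BED native).
#'
#' @param path BED file (3+ columns).
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if ("name" %in% names(mc)) out$name <- as.character(mc$name)
  if ("score" %in% names(mc) && !all(is.na(mc$score))) out$score <- mc$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' Export binding sites as BED6
#'
#' Writes one line per site with the log-odds score in the BED score column.
#'
#' @param sites site data.frame as from [scan_sequence()].
#' @param path output file.
#' @param chrom chromosome/region name for the first column.
#' @export
write_sites_bed <- function(sites, path, chrom = "region") {
  lines <- sprintf("%s\t%d\t%d\t%s\t%.10g\t%s",
                   chrom, sites$start, sites$end, sites$tf, sites$llr,
                   sites$strand)
  writeLines(lines, path)
  invisible(path)
}

#' TSS-relative site coordinates
#'
#' Adds `tss_start`/`tss_end` columns giving coordinates relative to the
#' region's transcription start site (negative = upstream).
#'
#' @param region a [regulatory_region()].
#' @return the site data.frame with TSS-relative columns appended.
#' @export
sites_relative_to_tss <- function(region) {
  s <- region$sites
  s$tss_start <- s$start - region$tss_offset
  s$tss_end <- s$end - region$tss_offset
  s
}
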