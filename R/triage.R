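# Candidate-selection cascade: class-code retention, structural filters,
# and the longest-ORF coding filter.

# gffcompare's documented single-character class codes
KNOWN_CLASS_CODES <- c("=", "c", "k", "m", "n", "j", "e", "o", "s", "x",
                       "i", "y", "p", "r", "u", ".")

#' Retain transcripts by gffcompare class code
#'
#' Novel-lncRNA discovery keeps transcripts whose relation to the reference
#' annotation is antisense ("x"), other-strand overlap ("o"), intronic
#' ("i"), intergenic ("u") or a novel isoform ("j"); exact or contained
#' matches of known transcripts are discarded.
#'
#' @param tx a `transcript_tbl` with a `class_code` column.
#' @param allowed character vector of retained class codes.
#' @return the retained subset, input order preserved.
#' @export
filter_by_class_code <- function(tx, allowed = c("x", "o", "i", "u", "j")) {
  code <- tx$class_code
  unknown <- !is.na(code) & !(code %in% KNOWN_CLASS_CODES)
  if (any(unknown))
    warning("unknown class code(s) dropped: ",
            paste(unique(code[unknown]), collapse = ", "))
  tx[!is.na(code) & code %in% allowed, , drop = FALSE]
}

#' Structural filter: minimum length and exon count
#'
#' Removes short (< 200 nt) and mono-exonic transcripts, which are enriched
#' for assembly artifacts and fragments.
#'
#' @param tx a `transcript_tbl`.
#' @param min_length minimum transcript length in nt (retained if >=).
#' @param min_exons minimum exon count (retained if >=).
#' @return the retained subset.
#' @export
filter_by_structure <- function(tx, min_length = 200L, min_exons = 2L) {
  keep <- transcript_length(tx) >= min_length & exon_count(tx) >= min_exons
  tx[keep, , drop = FALSE]
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame in the three forward frames
#'
#' Scans ATG-initiated codon runs in frames 0, 1 and 2 of the given strand
#' (assembled transcripts are already stranded, so the reverse complement
#' is not scanned). The reported length counts the ATG through the last
#' codon before the stop; the stop codon is excluded, so 100 aa
#' corresponds to 300 nt. A codon containing N terminates the current run
#' without counting as a stop. An open-ended run (no stop before the
#' sequence end) is reported with `has_stop = FALSE`. Ties are broken by
#' smallest start offset, then smallest frame.
#'
#' @param sequence a nucleotide string over A/C/G/T/N (case-insensitive).
#' @return a list with `start_offset` (0-based), `length_nt` (multiple of
#'   3; 0 when no ATG exists), `frame` (0/1/2) and `has_stop`.
#' @export
find_longest_orf <- function(sequence) {
  empty <- list(start_offset = NA_integer_, length_nt = 0L,
                frame = NA_integer_, has_stop = FALSE)
  if (is.na(sequence) || nchar(sequence) < 3L) return(empty)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  best <- empty
  for (frame in 0:2) {
    n_cod <- (L - frame) %/% 3L
    if (n_cod < 1L) next
    at <- frame + 3L * (seq_len(n_cod) - 1L) + 1L
    codons <- substring(sequence, at, at + 2L)
    terminator <- codons %in% STOP_CODONS | grepl("N", codons, fixed = TRUE)
    is_stop <- codons %in% STOP_CODONS
    # maximal codon stretches free of terminators
    bounds <- c(0L, which(terminator), n_cod + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      lo <- bounds[b] + 1L
      hi <- bounds[b + 1L] - 1L
      if (lo > hi) next
      atg <- which(codons[lo:hi] == "ATG")
      if (length(atg) == 0L) next
      a <- lo + atg[1L] - 1L
      len <- (hi - a + 1L) * 3L
      off <- frame + 3L * (a - 1L)
      stopped <- bounds[b + 1L] <= n_cod && is_stop[bounds[b + 1L]]
      if (len > best$length_nt ||
          (len == best$length_nt &&
           (off < best$start_offset ||
            (off == best$start_offset && frame < best$frame)))) {
        best <- list(start_offset = off, length_nt = len,
                     frame = frame, has_stop = stopped)
      }
    }
  }
  best
}

#' ORF-based coding filter
#'
#' By default drops transcripts whose longest ORF is >= `orf_threshold_nt`
#' (300 nt = 100 aa), i.e. transcripts with substantial coding capacity —
#' the standard direction for lncRNA candidate selection. The inverted
#' behaviour (`mode = "drop_short"`, retaining long-ORF transcripts) is
#' available for comparison.
#'
#' @param tx a `transcript_tbl` with sequences attached.
#' @param orf_threshold_nt ORF-length threshold in nt.
#' @param mode `"drop_long"` (default) retains transcripts with longest
#'   ORF < threshold; `"drop_short"` retains those with longest ORF >=
#'   threshold.
#' @return the retained subset.
#' @export
filter_by_orf <- function(tx, orf_threshold_nt = 300L,
                          mode = c("drop_long", "drop_short")) {
  mode <- match.arg(mode)
  if (anyNA(tx$sequence))
    stop("missing sequence for transcript(s): ",
         paste(utils::head(tx$transcript_id[is.na(tx$sequence)], 5),
               collapse = ", "))
  len <- vapply(tx$sequence, function(s) find_longest_orf(s)$length_nt,
                integer(1), USE.NAMES = FALSE)
  keep <- if (mode == "drop_long") len < orf_threshold_nt
          else len >= orf_threshold_nt
  tx[keep, , drop = FALSE]
}

#' Run the full candidate-selection cascade
#'
#' Applies, in order: class-code retention, the structural filter and the
#' ORF filter, and reports per-transcript status plus stage counts. The
#' statuses partition the input.
#'
#' @param tx a `transcript_tbl` with sequences attached.
#' @param allowed_codes retained class codes.
#' @param min_length,min_exons structural thresholds.
#' @param orf_threshold_nt,orf_mode ORF filter parameters
#'   (see [filter_by_orf()]).
#' @return a list of class `triage_report`: `retained` (the surviving
#'   `transcript_tbl`), `status` (named character vector over the input
#'   ids) and `counts` (input, dropped per stage, retained).
#' @export
run_triage <- function(tx, allowed_codes = c("x", "o", "i", "u", "j"),
                       min_length = 200L, min_exons = 2L,
                       orf_threshold_nt = 300L, orf_mode = "drop_long") {
  status <- stats::setNames(rep("retained", nrow(tx)), tx$transcript_id)
  s1 <- filter_by_class_code(tx, allowed_codes)
  status[setdiff(tx$transcript_id, s1$transcript_id)] <- "dropped_class_code"
  s2 <- filter_by_structure(s1, min_length, min_exons)
  status[setdiff(s1$transcript_id, s2$transcript_id)] <- "dropped_structure"
  s3 <- filter_by_orf(s2, orf_threshold_nt, orf_mode)
  status[setdiff(s2$transcript_id, s3$transcript_id)] <- "dropped_orf"
  counts <- c(input = nrow(tx),
              dropped_class_code = sum(status == "dropped_class_code"),
              dropped_structure = sum(status == "dropped_structure"),
              dropped_orf = sum(status == "dropped_orf"),
              retained = nrow(s3))
  structure(list(retained = s3, status = status, counts = counts),
            class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat("Transcript triage funnel\n")
  cat(sprintf("  input:               %6d\n", x$counts[["input"]]))
  cat(sprintf("  - class code:        %6d dropped\n",
              x$counts[["dropped_class_code"]]))
  cat(sprintf("  - length/exons:      %6d dropped\n",
              x$counts[["dropped_structure"]]))
  cat(sprintf("  - long ORF:          %6d dropped\n",
              x$counts[["dropped_orf"]]))
  cat(sprintf("  retained candidates: %6d\n", x$counts[["retained"]]))
  invisible(x)
}
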