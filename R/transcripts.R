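#' Build a transcript table
#'
#' The central container for assembled transcript models: one row per
#' transcript, with the exon chain held in two list-columns of 1-based
#' closed-interval coordinates (GTF convention). Exons are sorted by start
#' and must be pairwise non-overlapping.
#'
#' @param transcript_id character vector of unique transcript identifiers.
#' @param gene_id character vector of gene identifiers.
#' @param chrom character vector of chromosome names.
#' @param strand character vector, each element one of `"+"`, `"-"`, `"."`.
#' @param exon_starts,exon_ends lists of integer vectors, one per transcript,
#'   giving exon start/end positions (1-based, closed).
#' @param class_code single-character gffcompare class codes (e.g. `"u"`
#'   intergenic, `"="` exact reference match). May be `NA` for reference
#'   transcripts.
#' @param sequence optional character vector of nucleotide sequences; when
#'   present and non-`NA`, its length must equal the summed exon length.
#'
#' @return A `data.frame` of class `transcript_tbl`.
#' @export
transcript_table <- function(transcript_id, gene_id, chrom, strand,
                             exon_starts, exon_ends,
                             class_code = NA_character_,
                             sequence = NA_character_) {
  n <- length(transcript_id)
  stopifnot(length(gene_id) == n, length(chrom) == n, length(strand) == n,
            length(exon_starts) == n, length(exon_ends) == n)
  if (anyDuplicated(transcript_id))
    stop("duplicate transcript_id values")
  tx <- data.frame(transcript_id = as.character(transcript_id),
                   gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   class_code = rep_len(as.character(class_code), n),
                   stringsAsFactors = FALSE)
  tx$exon_starts <- unname(lapply(exon_starts, as.integer))
  tx$exon_ends <- unname(lapply(exon_ends, as.integer))
  tx$sequence <- rep_len(as.character(sequence), n)
  class(tx) <- c("transcript_tbl", "data.frame")
  validate_transcripts(tx)
  tx
}

#' Validate a transcript table
#'
#' Checks the exon-chain invariants (sorted, non-overlapping, end >= start)
#' and, where a sequence is attached, that its length equals the transcript
#' length.
#'
#' @param tx a `transcript_tbl`.
#' @return `tx`, invisibly, or an error naming the offending transcript.
#' @export
validate_transcripts <- function(tx) {
  for (i in seq_len(nrow(tx))) {
    s <- tx$exon_starts[[i]]; e <- tx$exon_ends[[i]]
    id <- tx$transcript_id[i]
    if (length(s) == 0L || length(s) != length(e))
      stop("transcript ", id, ": malformed exon chain")
    if (any(e < s))
      stop("transcript ", id, ": exon end < start")
    if (is.unsorted(s, strictly = TRUE) && length(s) > 1L)
      stop("transcript ", id, ": exons not sorted by start")
    if (length(s) > 1L && any(s[-1L] <= e[-length(e)]))
      stop("transcript ", id, ": overlapping exons")
    if (!is.na(tx$sequence[i]) &&
        nchar(tx$sequence[i]) != sum(e - s + 1L))
      stop("transcript ", id, ": sequence length != exon-chain length")
  }
  invisible(tx)
}

#' Transcript lengths
#'
#' Sum of exon lengths (end - start + 1) per transcript.
#'
#' @param tx a `transcript_tbl`.
#' @return integer vector named by transcript id.
#' @export
transcript_length <- function(tx) {
  len <- vapply(seq_len(nrow(tx)), function(i)
    sum(tx$exon_ends[[i]] - tx$exon_starts[[i]] + 1L), integer(1))
  stats::setNames(len, tx$transcript_id)
}

#' Exon counts per transcript
#' @param tx a `transcript_tbl`.
#' @return integer vector named by transcript id.
#' @export
exon_count <- function(tx) {
  stats::setNames(lengths(tx$exon_starts), tx$transcript_id)
}

#' Genomic span of each transcript
#'
#' First exon start to last exon end, as an integer matrix with columns
#' `start`, `end`.
#'
#' @param tx a `transcript_tbl`.
#' @return integer matrix, rows named by transcript id.
#' @export
transcript_span <- function(tx) {
  m <- cbind(start = vapply(tx$exon_starts, function(s) s[1L], integer(1)),
             end = vapply(tx$exon_ends, function(e) e[length(e)], integer(1)))
  rownames(m) <- tx$transcript_id
  m
}

#' Attach sequences to a transcript table
#'
#' @param tx a `transcript_tbl`.
#' @param seqs named character vector (or `Biostrings::DNAStringSet`) of
#'   nucleotide sequences keyed by transcript id.
#' @param require_all error if a transcript has no sequence (default TRUE).
#' @return `tx` with the `sequence` column filled.
#' @export
attach_sequences <- function(tx, seqs, require_all = TRUE) {
  if (methods::is(seqs, "DNAStringSet"))
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  hit <- match(tx$transcript_id, names(seqs))
  if (require_all && anyNA(hit))
    stop("no sequence for transcript(s): ",
         paste(utils::head(tx$transcript_id[is.na(hit)], 5), collapse = ", "))
  tx$sequence <- ifelse(is.na(hit), NA_character_, unname(seqs[hit]))
  validate_transcripts(tx)
  tx
}
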