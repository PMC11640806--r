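# Format-safe readers and writers. GTF goes through rtracklayer, FASTA
# through Biostrings; tabular intermediates are plain TSV so every stage
# output can be inspected and round-tripped.

#' Write a transcript table as GTF
#'
#' Emits one `exon` row per exon with `transcript_id`, `gene_id` and
#' (when present) `class_code` attributes, the gffcompare-annotated
#' dialect the triage stage consumes.
#'
#' @param tx a `transcript_tbl`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(tx, path) {
  n_ex <- lengths(tx$exon_starts)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(tx$chrom, n_ex),
    ranges = IRanges::IRanges(start = unlist(tx$exon_starts),
                              end = unlist(tx$exon_ends)),
    strand = ifelse(rep(tx$strand, n_ex) == ".", "*",
                    rep(tx$strand, n_ex)))
  S4Vectors::mcols(gr)$source <- "lncscreen"
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$transcript_id <- rep(tx$transcript_id, n_ex)
  S4Vectors::mcols(gr)$gene_id <- rep(tx$gene_id, n_ex)
  cc <- rep(tx$class_code, n_ex)
  if (!all(is.na(cc))) S4Vectors::mcols(gr)$class_code <- cc
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read transcripts from a GTF file
#'
#' Collects `exon` records into one transcript per `transcript_id`,
#' carrying `gene_id` and the gffcompare `class_code` attribute when
#' present.
#'
#' @param path GTF file path.
#' @return a `transcript_tbl`.
#' @export
read_gtf_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id))
    stop("GTF lacks transcript_id attribute: ", path)
  o <- order(mc$transcript_id, GenomicRanges::start(gr))
  gr <- gr[o]; mc <- S4Vectors::mcols(gr)
  tid <- mc$transcript_id
  first <- !duplicated(tid)
  transcript_table(
    transcript_id = tid[first],
    gene_id = if (!is.null(mc$gene_id)) mc$gene_id[first]
              else tid[first],
    chrom = as.character(GenomicRanges::seqnames(gr))[first],
    strand = sub("\\*", ".", as.character(BiocGenerics::strand(gr))[first]),
    exon_starts = split(GenomicRanges::start(gr), tid)[tid[first]],
    exon_ends = split(GenomicRanges::end(gr), tid)[tid[first]],
    class_code = if (!is.null(mc$class_code)) mc$class_code[first]
                 else NA_character_)
}

#' Write sequences as wrapped FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 60L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write / read a count matrix TSV (feature id index, sample columns)
#' @param counts integer matrix.
#' @param path file path.
#' @return `path` / integer matrix.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read a sample design TSV (sample, group)
#' @param design data.frame with `sample` and `group`.
#' @param path file path.
#' @return `path` / data.frame.
#' @export
write_design <- function(design, path) {
  utils::write.table(design[, c("sample", "group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a homology hit table TSV (outfmt-6 order + subject_type)
#' @param hits data.frame of hit records.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, HIT_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a term map TSV (gene, term, name, namespace)
#' @param tab long-format term table.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_term_map <- function(tab, path) {
  utils::write.table(tab[, c("gene", "term", "name", "namespace")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write planted ground truth as JSON
#' @param truth a `ground_truth`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(true_class = as.list(truth$true_class),
         true_de = as.list(truth$true_de),
         pairs = truth$pairs,
         cis_distances = truth$cis_distances,
         homology_group = as.list(truth$homology_group)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read planted ground truth JSON
#' @param path file path.
#' @return a `ground_truth` list.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(true_class = unlist(x$true_class),
                 true_de = unlist(x$true_de),
                 pairs = as.data.frame(x$pairs),
                 cis_distances = as.numeric(x$cis_distances),
                 homology_group = unlist(x$homology_group)),
            class = "ground_truth")
}
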