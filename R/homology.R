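# Homology triage: partition lncRNA candidates into three groups based on
# tabular nucleotide-homology hits (BLAST outfmt-6 dialect plus a
# subject_type column).

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore", "subject_type")

SUBJECT_TYPES <- c("protein_coding", "non_lncRNA", "lncRNA")

#' Read a tabular homology hit file
#'
#' Expects the 12 standard BLAST tabular (outfmt 6) columns followed by a
#' `subject_type` column with values `protein_coding`, `non_lncRNA` or
#' `lncRNA`. Accepts files with or without a header line.
#'
#' @param path file path.
#' @return data.frame of hit records.
#' @export
read_hit_table <- function(path) {
  first <- readLines(path, n = 1L)
  header <- startsWith(first, "qseqid")
  hits <- if (header)
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  else
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = HIT_COLUMNS, stringsAsFactors = FALSE)
  if (ncol(hits) != length(HIT_COLUMNS))
    stop("hit table must have ", length(HIT_COLUMNS), " columns, found ",
         ncol(hits))
  names(hits) <- HIT_COLUMNS
  validate_hits(hits)
  hits
}

validate_hits <- function(hits) {
  if (any(hits$evalue < 0)) stop("negative e-value in hit table")
  bad <- setdiff(unique(hits$subject_type), SUBJECT_TYPES)
  if (length(bad))
    stop("unknown subject_type value(s): ", paste(bad, collapse = ", "))
  invisible(hits)
}

#' Three-group homology triage of lncRNA candidates
#'
#' A hit is significant iff its e-value is <= `evalue_max`. Candidates
#' with a significant hit to a protein-coding gene or other non-lncRNA
#' transcript form group 1 (excluded downstream); candidates whose best
#' significant evidence is a known lncRNA form group 2; candidates with no
#' significant hit form group 3. Groups 2 and 3 are carried forward as
#' novel lncRNAs. When a candidate has significant hits of conflicting
#' subject types, the coding/non-lncRNA evidence dominates (conservative
#' exclusion). The three groups always partition the candidate set.
#'
#' @param candidate_ids character vector of candidate transcript ids.
#' @param hits data.frame of hit records (see [read_hit_table()]). Hits
#'   whose query is not a candidate are warned about and ignored.
#' @param evalue_max significance threshold on the e-value (default 1e-5).
#' @return a list of class `homology_groups` with `group1_excluded`,
#'   `group2_known_lncrna`, `group3_no_match` (character vectors) and
#'   `retained` (= groups 2 and 3, input order).
#' @export
classify_by_homology <- function(candidate_ids, hits, evalue_max = 1e-5) {
  validate_hits(hits)
  stray <- setdiff(unique(hits$qseqid), candidate_ids)
  if (length(stray)) {
    warning(length(stray), " hit query id(s) not among candidates ignored")
    hits <- hits[hits$qseqid %in% candidate_ids, , drop = FALSE]
  }
  sig <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  coding_ids <- unique(sig$qseqid[sig$subject_type %in%
                                    c("protein_coding", "non_lncRNA")])
  lnc_ids <- setdiff(unique(sig$qseqid[sig$subject_type == "lncRNA"]),
                     coding_ids)
  g1 <- candidate_ids[candidate_ids %in% coding_ids]
  g2 <- candidate_ids[candidate_ids %in% lnc_ids]
  g3 <- candidate_ids[!(candidate_ids %in% c(coding_ids, lnc_ids))]
  structure(list(group1_excluded = g1,
                 group2_known_lncrna = g2,
                 group3_no_match = g3,
                 retained = candidate_ids[candidate_ids %in% c(g2, g3)]),
            class = "homology_groups")
}

#' @export
print.homology_groups <- function(x, ...) {
  cat("Homology triage:\n")
  cat("  group 1 (coding/non-lncRNA match, excluded):",
      length(x$group1_excluded), "\n")
  cat("  group 2 (known lncRNA match, retained):    ",
      length(x$group2_known_lncrna), "\n")
  cat("  group 3 (no significant match, retained): ",
      length(x$group3_no_match), "\n")
  invisible(x)
}
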