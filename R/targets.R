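# Regulatory target inference: Pearson co-expression screening of
# DEL-DEG pairs, genomic-distance computation, cis (< 20 kb) vs trans
# assignment, and network summarisation.

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r with the t-based two-sided p-value,
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#' |r| = 1 gives p = 0 exactly.
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return list(`r`, `p`), or `NULL` with a warning when either vector has
#'   zero variance (r undefined; the pair is skipped by callers).
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length vectors with n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance vector: correlation undefined, pair skipped")
    return(NULL)
  }
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) >= 1) return(list(r = sign(r), p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

#' Screen DEL-DEG pairs by expression correlation
#'
#' Correlates every DEL expression profile against every DEG profile
#' (rows = features, columns = shared samples; both groups pooled, on the
#' log2 normalized scale) and retains pairs with |r| >= `min_abs_r` and
#' p < `p_max`. Retained pairs start as trans; [assign_cis()] reassigns
#' the genomically proximal ones. Zero-variance features are skipped with
#' a warning.
#'
#' @param del_expr,deg_expr numeric matrices with identical column
#'   (sample) sets; rows named by feature id.
#' @param min_abs_r correlation magnitude threshold (default 0.90).
#' @param p_max p-value threshold (strict `<`; default 0.01).
#' @return data.frame of pairs: `del_id`, `deg_id`, `r`, `r_squared`,
#'   `p_value`, `sign` (`positive`/`negative`), `mode` (all `trans`),
#'   `distance_bp` (NA).
#' @export
infer_trans_targets <- function(del_expr, deg_expr, min_abs_r = 0.90,
                                p_max = 0.01) {
  if (!identical(colnames(del_expr), colnames(deg_expr))) {
    common <- intersect(colnames(del_expr), colnames(deg_expr))
    if (length(common) == 0L) stop("expression matrices share no samples")
    del_expr <- del_expr[, common, drop = FALSE]
    deg_expr <- deg_expr[, common, drop = FALSE]
  }
  n <- ncol(del_expr)
  if (n < 3L) stop("need >= 3 shared samples")
  sd_del <- apply(del_expr, 1, stats::sd)
  sd_deg <- apply(deg_expr, 1, stats::sd)
  if (any(sd_del == 0) || any(sd_deg == 0))
    warning("zero-variance feature(s) skipped: ",
            paste(c(rownames(del_expr)[sd_del == 0],
                    rownames(deg_expr)[sd_deg == 0]), collapse = ", "))
  del_expr <- del_expr[sd_del > 0, , drop = FALSE]
  deg_expr <- deg_expr[sd_deg > 0, , drop = FALSE]
  R <- stats::cor(t(del_expr), t(deg_expr))
  R <- pmin(pmax(R, -1), 1)
  tt <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * stats::pt(-abs(tt), df = n - 2)
  P[abs(R) >= 1] <- 0
  hit <- which(abs(R) >= min_abs_r & P < p_max, arr.ind = TRUE)
  pairs <- data.frame(del_id = rownames(R)[hit[, 1]],
                      deg_id = colnames(R)[hit[, 2]],
                      r = R[hit], r_squared = R[hit]^2,
                      p_value = P[hit],
                      sign = ifelse(R[hit] > 0, "positive", "negative"),
                      mode = rep("trans", nrow(hit)),
                      distance_bp = rep(NA_real_, nrow(hit)),
                      row.names = NULL, stringsAsFactors = FALSE)
  pairs[order(pairs$del_id, pairs$deg_id), , drop = FALSE]
}

#' Genomic distance between two transcript spans
#'
#' Uses each transcript's span (first exon start to last exon end,
#' 1-based closed). Overlapping spans have distance 0; otherwise the gap
#' in bp between the nearer span ends. Strand is ignored.
#'
#' @param span_a,span_b length-2 integer vectors `c(start, end)`.
#' @param chrom_a,chrom_b chromosome names.
#' @return non-negative integer, or `NA` (different chromosomes).
#' @export
genomic_distance <- function(span_a, chrom_a, span_b, chrom_b) {
  if (chrom_a != chrom_b) return(NA_integer_)
  if (span_a[1] <= span_b[2] && span_b[1] <= span_a[2]) return(0L)
  if (span_a[2] < span_b[1]) as.integer(span_b[1] - span_a[2] - 1L)
  else as.integer(span_a[1] - span_b[2] - 1L)
}

#' Assign cis vs trans mode to correlated pairs
#'
#' A retained pair is cis iff both features lie on the same chromosome
#' with a span gap strictly below `max_distance_bp` (default 20 kb);
#' every other pair is trans. The pair count is conserved.
#'
#' @param pairs data.frame from [infer_trans_targets()].
#' @param annotation a `transcript_tbl` covering every id in `pairs`
#'   (for genes, any transcript row carrying the gene's span).
#' @param max_distance_bp cis window in bp (strict `<`).
#' @return `pairs` with `mode` and `distance_bp` filled.
#' @export
assign_cis <- function(pairs, annotation, max_distance_bp = 20000L) {
  if (nrow(pairs) == 0L) return(pairs)
  ids <- unique(c(pairs$del_id, pairs$deg_id))
  missing <- setdiff(ids, annotation$transcript_id)
  if (length(missing))
    stop("id(s) missing from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  sp <- transcript_span(annotation)
  ch <- stats::setNames(annotation$chrom, annotation$transcript_id)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$del_id[i]; b <- pairs$deg_id[i]
    d <- genomic_distance(sp[a, ], ch[[a]], sp[b, ], ch[[b]])
    pairs$distance_bp[i] <- as.numeric(d)
    pairs$mode[i] <- if (!is.na(d) && d < max_distance_bp) "cis" else "trans"
  }
  pairs
}

#' Summarise a regulatory-pair network
#'
#' Tallies pairs by sign and mode and lists dual-mode DELs — lncRNAs
#' appearing in at least one cis and at least one trans pair, the pattern
#' of locally-acting lncRNAs that also reach distant loci.
#'
#' @param pairs finalized pair data.frame.
#' @return list of class `network_summary`: `n_pairs`, `n_positive`,
#'   `n_negative`, `n_cis`, `n_trans`, `dual_mode_del_ids`.
#' @export
summarize_network <- function(pairs) {
  cis_dels <- unique(pairs$del_id[pairs$mode == "cis"])
  trans_dels <- unique(pairs$del_id[pairs$mode == "trans"])
  structure(list(n_pairs = nrow(pairs),
                 n_positive = sum(pairs$sign == "positive"),
                 n_negative = sum(pairs$sign == "negative"),
                 n_cis = sum(pairs$mode == "cis"),
                 n_trans = sum(pairs$mode == "trans"),
                 dual_mode_del_ids = sort(intersect(cis_dels, trans_dels))),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Regulatory pairs:", x$n_pairs,
      sprintf("(%d positive, %d negative; %d cis, %d trans)\n",
              x$n_positive, x$n_negative, x$n_cis, x$n_trans))
  cat("Dual-mode (cis+trans) DELs:", length(x$dual_mode_del_ids), "\n")
  invisible(x)
}
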