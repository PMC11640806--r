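# Two-group differential expression: median-of-ratios normalization,
# method-of-moments dispersion estimation with trend shrinkage, a
# negative-binomial Wald test, Benjamini-Hochberg adjustment, DE calling,
# and the sample-similarity / feature-structure summaries.

#' Median-of-ratios size factors
#'
#' For each feature positive in every sample, the ratio of its count to
#' its geometric mean across samples is formed; the per-sample size factor
#' is the median of those ratios. This makes samples comparable without
#' assuming equal library composition.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @return positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos))
    stop("no feature has positive counts in every sample; ",
         "filter or aggregate features first")
  geo <- exp(rowMeans(log(counts[allpos, , drop = FALSE])))
  sf <- apply(counts[allpos, , drop = FALSE] / geo, 2, stats::median)
  stats::setNames(sf, colnames(counts))
}

#' Normalized counts
#' @param counts features x samples matrix.
#' @param sf size factors from [size_factors()].
#' @return matrix of counts divided by their sample's size factor.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  sweep(as.matrix(counts), 2, sf, "/")
}

# Per-feature NB dispersion: method-of-moments on normalized counts using
# pooled within-group variance, floored, then shrunk halfway toward a
# fitted mean-dispersion trend alpha(mu) = a0 + a1/mu. The trend pools
# information across features, stabilising the noisy per-feature moments
# at n = 4 per group.
estimate_dispersions <- function(norm, group, floor = 1e-8) {
  groups <- unique(group)
  n <- ncol(norm)
  xim <- mean(1 / attr(norm, "sf", exact = TRUE) %||% rep(1, n))
  mu <- rowMeans(norm)
  # pooled within-group variance
  v <- rep(0, nrow(norm))
  df <- 0
  for (g in groups) {
    idx <- group == g
    ng <- sum(idx)
    if (ng > 1) {
      v <- v + apply(norm[, idx, drop = FALSE], 1, stats::var) * (ng - 1)
      df <- df + (ng - 1)
    }
  }
  v <- v / df
  raw <- pmax((v - xim * mu) / mu^2, floor)
  raw[!is.finite(raw)] <- floor
  # least-squares trend over informative features
  use <- raw > floor & mu > 0
  if (sum(use) >= 10) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[use]), raw[use])
    trend <- pmax(fit$coefficients[1] + fit$coefficients[2] / mu, floor)
  } else {
    trend <- rep(max(stats::median(raw), floor), length(raw))
  }
  pmax(0.5 * raw + 0.5 * trend, floor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Negative-binomial Wald test for a two-group design
#'
#' Counts are normalized by median-of-ratios size factors; per-feature NB
#' dispersions are estimated by method of moments on the normalized counts
#' (pooled within-group variance), floored at 1e-8 and shrunk halfway
#' toward a least-squares mean-dispersion trend a0 + a1/mu. The log2 fold
#' change is the log2 ratio of group means of normalized counts, with a
#' pseudo-count of 0.5 added to both means so zero-expression groups give
#' finite estimates. Its standard error follows from the NB variance by
#' the delta method, and the Wald statistic log2FC/SE is referred to a
#' standard normal for a two-sided p-value. P-values are BH-adjusted.
#' All-zero features are reported with log2FC 0, p 1 and flagged.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param design data.frame with columns `sample` and `group`, or a named
#'   group factor/character over the samples.
#' @param reference reference group label; the contrast is the other group
#'   over this one (positive log2FC = higher in contrast).
#' @param sf optional size factors (computed if missing).
#' @param feature_class optional named map feature id -> class (e.g.
#'   `"lncRNA"`/`"mRNA"`), copied into the result.
#' @return data.frame (one row per feature): `feature_id`, `base_mean`,
#'   `log2fc`, `se_log2fc`, `wald_stat`, `p_value`, `p_adjusted`,
#'   `all_zero`, and `feature_class` when supplied.
#' @export
nb_wald_test <- function(counts, design, reference = NULL, sf = NULL,
                         feature_class = NULL) {
  counts <- as.matrix(counts)
  group <- design_groups(design, colnames(counts))
  labs <- unique(group)
  if (length(labs) != 2L) stop("design must have exactly two groups")
  if (min(table(group)) < 2L) stop("need >= 2 samples per group")
  if (is.null(reference)) reference <- labs[1L]
  if (!reference %in% labs) stop("reference group not in design")
  contrast <- setdiff(labs, reference)
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)
  attr(norm, "sf") <- sf

  alpha <- estimate_dispersions(norm, group)
  iref <- group == reference
  icon <- group == contrast
  m_ref <- rowMeans(norm[, iref, drop = FALSE]) + 0.5
  m_con <- rowMeans(norm[, icon, drop = FALSE]) + 0.5
  lfc <- log2(m_con / m_ref)
  # Var(mean of normalized counts) for NB(q*sf, alpha):
  #   (1/n^2) * sum_s (q/sf_s + alpha q^2)
  vmean <- function(q, idx) {
    n <- sum(idx)
    (q * sum(1 / sf[idx]) + alpha * q^2 * n) / n^2
  }
  se <- sqrt((vmean(m_ref, iref) / m_ref^2 +
                vmean(m_con, icon) / m_con^2)) / log(2)
  stat <- lfc / se
  p <- 2 * stats::pnorm(-abs(stat))

  zero <- rowSums(counts) == 0
  lfc[zero] <- 0; stat[zero] <- 0; p[zero] <- 1; se[zero] <- NA_real_
  res <- data.frame(feature_id = rownames(counts),
                    base_mean = rowMeans(norm),
                    log2fc = lfc, se_log2fc = se, wald_stat = stat,
                    p_value = p, p_adjusted = bh_adjust(p),
                    all_zero = zero, row.names = NULL)
  if (!is.null(feature_class))
    res$feature_class <- unname(feature_class[res$feature_id])
  attr(res, "contrast") <- c(contrast = contrast, reference = reference)
  res
}

design_groups <- function(design, samples) {
  if (is.data.frame(design)) {
    if (!all(c("sample", "group") %in% names(design)))
      stop("design needs 'sample' and 'group' columns")
    g <- stats::setNames(as.character(design$group),
                         as.character(design$sample))
  } else {
    g <- stats::setNames(as.character(design), names(design))
  }
  if (!all(samples %in% names(g)))
    stop("sample(s) missing from design: ",
         paste(setdiff(samples, names(g)), collapse = ", "))
  unname(g[samples])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR control: order the m p-values, multiply the i-th
#' smallest by m/i, enforce monotonicity from the largest down, cap at 1.
#' Input order is preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Call differentially expressed features
#'
#' A feature is DE iff its adjusted p-value is strictly below `padj_max`
#' and |log2FC| is at least `min_abs_log2fc`. Direction is annotated from
#' the sign of log2FC. When the results carry a `feature_class` column the
#' DE set is split into DELs (lncRNA) and DEGs (mRNA).
#'
#' @param results data.frame from [nb_wald_test()].
#' @param padj_max adjusted-p threshold (strict `<`; default 0.05).
#' @param min_abs_log2fc fold-change threshold (non-strict `>=`; default 1).
#' @return `results` with `is_de` and `direction` columns, plus attributes
#'   `dels` and `degs` (data.frames) when `feature_class` is present.
#' @export
call_de <- function(results, padj_max = 0.05, min_abs_log2fc = 1.0) {
  results$is_de <- results$p_adjusted < padj_max &
    abs(results$log2fc) >= min_abs_log2fc
  results$direction <- ifelse(!results$is_de, "ns",
                              ifelse(results$log2fc > 0, "up", "down"))
  if (!is.null(results$feature_class)) {
    attr(results, "dels") <-
      results[results$is_de & results$feature_class == "lncRNA", ,
              drop = FALSE]
    attr(results, "degs") <-
      results[results$is_de & results$feature_class == "mRNA", ,
              drop = FALSE]
  }
  results
}

#' Sample-similarity summaries: PCA and distance matrix
#'
#' Computed on log2(normalized count + 1). PCA is the singular value
#' decomposition of the centered sample matrix (samples as observations);
#' the distance matrix is Euclidean.
#'
#' @param counts features x samples matrix.
#' @param sf size factors (computed if missing).
#' @return list: `pca` (data.frame sample, PC1, PC2), `var_explained`
#'   (fraction per PC), `dist` (symmetric matrix, zero diagonal).
#' @export
sample_similarity <- function(counts, sf = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 3L) stop("need at least 3 samples")
  logm <- log2(normalize_counts(counts, sf) + 1)
  x <- t(logm)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(pca = data.frame(sample = colnames(counts),
                        PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                        row.names = NULL),
       var_explained = ve,
       dist = as.matrix(stats::dist(x)))
}

#' Structural comparison of lncRNA and mRNA transcripts
#'
#' Per class: mean and SEM of transcript length, exon length (pooling all
#' exons) and exon number, plus binned distributions (length bins <1500,
#' 1500-3000, >3000 nt; exon-count bins <=3, 4-10, >10).
#'
#' @param tx a `transcript_tbl`.
#' @param labels named character map transcript id -> `"lncRNA"`/`"mRNA"`.
#' @return list with `summary` (data.frame class, metric, mean, sem,
#'   n, sem_degenerate), `length_bins` and `exon_bins` (count tables).
#' @export
compare_feature_structure <- function(tx, labels) {
  cls <- unname(labels[tx$transcript_id])
  if (length(unique(stats::na.omit(cls))) < 2L)
    stop("both classes must be non-empty")
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  rows <- list()
  lb <- list(); eb <- list()
  for (cl in sort(unique(stats::na.omit(cls)))) {
    sub <- tx[!is.na(cls) & cls == cl, , drop = FALSE]
    len <- transcript_length(sub)
    nex <- exon_count(sub)
    exlen <- unlist(lapply(seq_len(nrow(sub)), function(i)
      sub$exon_ends[[i]] - sub$exon_starts[[i]] + 1L))
    for (metric in c("transcript_length", "exon_length", "exon_number")) {
      x <- switch(metric, transcript_length = len, exon_length = exlen,
                  exon_number = nex)
      rows[[length(rows) + 1L]] <-
        data.frame(class = cl, metric = metric, mean = mean(x),
                   sem = sem(x), n = length(x),
                   sem_degenerate = length(x) < 2)
    }
    lb[[cl]] <- table(cut(len, c(-Inf, 1499.5, 3000.5, Inf),
                          labels = c("<1500", "1500-3000", ">3000")))
    eb[[cl]] <- table(cut(nex, c(-Inf, 3.5, 10.5, Inf),
                          labels = c("<=3", "4-10", ">10")))
  }
  list(summary = do.call(rbind, rows), length_bins = lb, exon_bins = eb)
}
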