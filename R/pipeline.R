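# End-to-end orchestration: simulate -> triage -> classify -> homology ->
# differential expression -> cis/trans targets -> enrichment, with a
# machine-readable run report mirroring the stage funnel.

#' Pipeline run configuration
#'
#' Bundles input paths and every stage threshold. Defaults encode the
#' pipeline's canonical values: class codes {x,o,i,u,j}; >= 200 nt and
#' >= 2 exons; 300 nt ORF cutoff (dropping long-ORF transcripts);
#' homology significance E <= 1e-5; DE at adjusted p < 0.05 and
#' |log2FC| >= 1; pair screening at |r| >= 0.90 and p < 0.01; cis window
#' < 20 kb; enrichment at adjusted p <= 0.05.
#'
#' @param novel_gtf,transcript_fasta novel-transcript annotation and
#'   sequences.
#' @param reference_gtf reference annotation (for cis/trans distances).
#' @param training_coding_fasta,training_noncoding_fasta classifier
#'   training sequences.
#' @param counts_tsv,design_tsv count matrix and sample->group design.
#' @param hits_tsv homology hit table.
#' @param term_map_tsv gene->term annotation map.
#' @param outdir output directory.
#' @param allowed_codes,min_length,min_exons,orf_threshold_nt,orf_mode
#'   triage thresholds.
#' @param k_folds,n_trees classifier settings.
#' @param evalue_max homology significance threshold.
#' @param reference_group reference group label (contrast is the other
#'   group over this one).
#' @param padj_max,min_abs_log2fc DE thresholds.
#' @param min_abs_r,trans_p_max,cis_max_distance_bp target-pair
#'   thresholds.
#' @param enrich_padj_max,min_term_size enrichment thresholds.
#' @param seed integer seed for the stochastic stages.
#' @return a list of class `run_config`.
#' @export
run_config <- function(novel_gtf, transcript_fasta, reference_gtf,
                       training_coding_fasta, training_noncoding_fasta,
                       counts_tsv, design_tsv, hits_tsv, term_map_tsv,
                       outdir,
                       allowed_codes = c("x", "o", "i", "u", "j"),
                       min_length = 200L, min_exons = 2L,
                       orf_threshold_nt = 300L, orf_mode = "drop_long",
                       k_folds = 10L, n_trees = 500L,
                       evalue_max = 1e-5,
                       reference_group = NULL,
                       padj_max = 0.05, min_abs_log2fc = 1.0,
                       min_abs_r = 0.90, trans_p_max = 0.01,
                       cis_max_distance_bp = 20000L,
                       enrich_padj_max = 0.05, min_term_size = 3L,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Write a complete synthetic input bundle
#'
#' Runs all generators for one [sim_config()] and writes the files a
#' pipeline run consumes, plus the planted-truth JSON. Returns a ready
#' [run_config()] pointing at them.
#'
#' @param sim a [sim_config()].
#' @param dir output directory (created if needed).
#' @return a `run_config` for [run_pipeline()].
#' @export
simulate_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(sim)
  seqs <- simulate_sequences(ann$novel, sim, ann$truth)
  corpus <- simulate_training_corpus(sim)
  cnt <- simulate_counts(sim, ann$truth)
  hits <- simulate_hit_table(ann$novel, ann$truth, sim)
  gene_ids <- sprintf("GENE_%04d", seq_len(sim$n_reference_genes))
  planted_degs <- intersect(names(ann$truth$true_de), gene_ids)
  tm <- simulate_term_map(gene_ids, sim, planted_genes = planted_degs)

  p <- function(f) file.path(dir, f)
  write_gtf(ann$novel, p("novel.gtf"))
  write_gtf(ann$reference, p("reference.gtf"))
  write_fasta(seqs, p("transcripts.fa"))
  write_fasta(corpus$coding, p("training_coding.fa"))
  write_fasta(corpus$noncoding, p("training_noncoding.fa"))
  write_counts(cnt$counts, p("counts.tsv"))
  write_design(cnt$design, p("design.tsv"))
  write_hit_table(hits, p("hits.tsv"))
  write_term_map(tm, p("term_map.tsv"))
  write_truth(ann$truth, p("truth.json"))

  run_config(novel_gtf = p("novel.gtf"),
             transcript_fasta = p("transcripts.fa"),
             reference_gtf = p("reference.gtf"),
             training_coding_fasta = p("training_coding.fa"),
             training_noncoding_fasta = p("training_noncoding.fa"),
             counts_tsv = p("counts.tsv"), design_tsv = p("design.tsv"),
             hits_tsv = p("hits.tsv"), term_map_tsv = p("term_map.tsv"),
             outdir = file.path(dir, "out"),
             reference_group = sim$groups[1], seed = sim$seed)
}

#' Validate pipeline inputs
#'
#' Schema checks returned as findings, not thrown: GTF attribute
#' presence, FASTA/GTF id agreement, counts/design sample agreement, hit
#' table column count.
#'
#' @param config a `run_config`.
#' @return data.frame with `level` (`error`/`warning`) and `message`;
#'   zero rows when fully consistent.
#' @export
validate_inputs <- function(config) {
  findings <- list()
  note <- function(level, msg)
    findings[[length(findings) + 1L]] <<-
      data.frame(level = level, message = msg, stringsAsFactors = FALSE)
  tx <- tryCatch(read_gtf_transcripts(config$novel_gtf),
                 error = function(e) {
                   note("error", paste("novel GTF:", conditionMessage(e)))
                   NULL
                 })
  if (!is.null(tx)) {
    if (all(is.na(tx$class_code)))
      note("error", "novel GTF lacks class_code attribute")
    seqs <- tryCatch(read_fasta(config$transcript_fasta),
                     error = function(e) NULL)
    if (is.null(seqs)) {
      note("error", "transcript FASTA unreadable")
    } else {
      missing <- setdiff(tx$transcript_id, names(seqs))
      if (length(missing))
        note("error", paste0(length(missing),
                             " GTF transcript(s) missing from FASTA"))
    }
  }
  counts <- tryCatch(read_counts(config$counts_tsv),
                     error = function(e) NULL)
  design <- tryCatch(read_design(config$design_tsv),
                     error = function(e) NULL)
  if (is.null(counts)) note("error", "counts TSV unreadable")
  if (is.null(design)) note("error", "design TSV unreadable")
  if (!is.null(counts) && !is.null(design)) {
    extra <- setdiff(colnames(counts), design$sample)
    if (length(extra))
      note("error", paste("counts column(s) not in design:",
                          paste(extra, collapse = ", ")))
  }
  hits_ok <- tryCatch({
    read_hit_table(config$hits_tsv); TRUE
  }, error = function(e) {
    note("error", paste("hit table:", conditionMessage(e)))
    FALSE
  })
  invisible(hits_ok)
  if (length(findings) == 0L)
    return(data.frame(level = character(0), message = character(0)))
  do.call(rbind, findings)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline failed at stage '", name, "': ",
         conditionMessage(e), call. = FALSE))
}

#' Run the full discovery and regulatory-inference pipeline
#'
#' Executes triage, coding-potential classification, homology triage,
#' differential expression, cis/trans target inference and enrichment in
#' order, writing every stage table under `config$outdir` and returning
#' a run report whose counts reconstruct the stage funnel. Identical
#' config and seed give identical outputs.
#'
#' @param config a `run_config`.
#' @return a list of class `run_report` (also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$outdir, f)

  tx <- stage("read_inputs", {
    tx <- read_gtf_transcripts(config$novel_gtf)
    attach_sequences(tx, read_fasta(config$transcript_fasta))
  })

  triage <- stage("triage", run_triage(
    tx, allowed_codes = config$allowed_codes,
    min_length = config$min_length, min_exons = config$min_exons,
    orf_threshold_nt = config$orf_threshold_nt,
    orf_mode = config$orf_mode))
  utils::write.table(
    data.frame(transcript_id = names(triage$status),
               status = unname(triage$status)),
    p("triage.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  cls <- stage("classify", {
    training <- build_training_set(
      read_fasta(config$training_coding_fasta),
      read_fasta(config$training_noncoding_fasta))
    model <- train_classifier(training, k_folds = config$k_folds,
                              seed = config$seed,
                              n_trees = config$n_trees)
    pred <- predict_lncrna(model, triage$retained)
    utils::write.table(pred$predictions, p("predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(model = model, pred = pred)
  })

  hom <- stage("homology", {
    hits <- read_hit_table(config$hits_tsv)
    classify_by_homology(cls$pred$lncrna$transcript_id, hits,
                         evalue_max = config$evalue_max)
  })
  lnc_ids <- hom$retained
  utils::write.table(
    data.frame(transcript_id = c(hom$group1_excluded,
                                 hom$group2_known_lncrna,
                                 hom$group3_no_match),
               group = rep(1:3, c(length(hom$group1_excluded),
                                  length(hom$group2_known_lncrna),
                                  length(hom$group3_no_match)))),
    p("homology_groups.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  de <- stage("diffexpr", {
    counts <- read_counts(config$counts_tsv)
    design <- read_design(config$design_tsv)
    if (nrow(counts) == 0L) stop("counts matrix is empty")
    keep <- rownames(counts)[!(rownames(counts) %in% tx$transcript_id) |
                               rownames(counts) %in% lnc_ids]
    counts <- counts[keep, , drop = FALSE]
    fclass <- stats::setNames(
      ifelse(rownames(counts) %in% lnc_ids, "lncRNA", "mRNA"),
      rownames(counts))
    ref <- config$reference_group %||% design$group[1]
    res <- nb_wald_test(counts, design, reference = ref,
                        feature_class = fclass)
    res <- call_de(res, padj_max = config$padj_max,
                   min_abs_log2fc = config$min_abs_log2fc)
    utils::write.table(res, p("de_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sim <- sample_similarity(counts)
    utils::write.table(sim$pca, p("pca.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$dist, p("sample_dist.tsv"), sep = "\t",
                       quote = FALSE)
    list(results = res, counts = counts, design = design)
  })
  dels <- attr(de$results, "dels")
  degs <- attr(de$results, "degs")

  pairs <- stage("targets", {
    if (nrow(dels) > 0 && nrow(degs) > 0) {
      expr <- log2(normalize_counts(de$counts) + 1)
      pr <- infer_trans_targets(
        expr[dels$feature_id, , drop = FALSE],
        expr[degs$feature_id, , drop = FALSE],
        min_abs_r = config$min_abs_r, p_max = config$trans_p_max)
      ref_tx <- read_gtf_transcripts(config$reference_gtf)
      ref_tx$transcript_id <- ref_tx$gene_id
      annot <- rbind_tx(ref_tx, tx)
      assign_cis(pr, annot,
                 max_distance_bp = config$cis_max_distance_bp)
    } else {
      data.frame(del_id = character(0), deg_id = character(0),
                 r = numeric(0), r_squared = numeric(0),
                 p_value = numeric(0), sign = character(0),
                 mode = character(0), distance_bp = numeric(0))
    }
  })
  utils::write.table(pairs, p("pairs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  net <- summarize_network(pairs)

  enr <- stage("enrichment", {
    targets <- unique(pairs$deg_id)
    if (length(targets) > 0 && file.exists(config$term_map_tsv)) {
      map <- read_term_map(config$term_map_tsv)
      expressed <- rownames(de$counts)
      res <- tryCatch(
        enrich(targets, map, padj_max = config$enrich_padj_max,
               min_term_size = config$min_term_size,
               expressed = expressed),
        error = function(e) NULL)
      if (!is.null(res))
        utils::write.table(res, p("enrichment.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      res
    } else NULL
  })

  report <- structure(list(
    version = as.character(utils::packageVersion("lncscreen")),
    seed = config$seed,
    thresholds = config[c("allowed_codes", "min_length", "min_exons",
                          "orf_threshold_nt", "orf_mode", "evalue_max",
                          "padj_max", "min_abs_log2fc", "min_abs_r",
                          "trans_p_max", "cis_max_distance_bp",
                          "enrich_padj_max", "min_term_size")],
    counts = list(
      transcripts_in = unname(triage$counts[["input"]]),
      dropped_class_code = unname(triage$counts[["dropped_class_code"]]),
      dropped_structure = unname(triage$counts[["dropped_structure"]]),
      dropped_orf = unname(triage$counts[["dropped_orf"]]),
      triage_retained = unname(triage$counts[["retained"]]),
      predicted_lncrna = nrow(cls$pred$lncrna),
      homology_group1 = length(hom$group1_excluded),
      homology_group2 = length(hom$group2_known_lncrna),
      homology_group3 = length(hom$group3_no_match),
      lncrna_final = length(lnc_ids),
      dels_total = nrow(dels),
      dels_up = sum(dels$direction == "up"),
      dels_down = sum(dels$direction == "down"),
      degs_total = nrow(degs),
      degs_up = sum(degs$direction == "up"),
      degs_down = sum(degs$direction == "down"),
      pairs_total = net$n_pairs,
      pairs_positive = net$n_positive,
      pairs_negative = net$n_negative,
      pairs_cis = net$n_cis,
      pairs_trans = net$n_trans,
      dual_mode_dels = length(net$dual_mode_del_ids),
      enriched_terms = if (is.null(enr)) 0L else sum(enr$enriched))),
    class = "run_report")
  jsonlite::write_json(unclass(report), p("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("lncscreen run (seed", x$seed, ")\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-20s %6d\n", nm, x$counts[[nm]]))
  invisible(x)
}
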