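# Coding-potential classification: deduplicated training corpus, sequence
# feature extraction, random-forest training with stratified k-fold CV,
# and lncRNA/mRNA prediction for candidate transcripts.

#' Build a deduplicated labeled training set
#'
#' Exact-duplicate nucleotide sequences are collapsed to one record (the
#' first id wins); a sequence appearing under both labels carries no usable
#' signal and is removed entirely (the conflict is recorded and warned).
#'
#' @param coding_seqs,noncoding_seqs named character vectors (or
#'   `DNAStringSet`s) of nucleotide sequences.
#' @return a list of class `labeled_seqs`: `id`, `sequence`, `label`
#'   (parallel vectors, label in `{"coding","noncoding"}`) and
#'   `conflicts` (ids removed for cross-label duplication).
#' @export
build_training_set <- function(coding_seqs, noncoding_seqs) {
  as_chr <- function(x) {
    if (methods::is(x, "DNAStringSet"))
      x <- stats::setNames(as.character(x), names(x))
    toupper(x)
  }
  cod <- as_chr(coding_seqs); nc <- as_chr(noncoding_seqs)
  if (length(cod) == 0L || length(nc) == 0L)
    stop("both coding and noncoding sequence sets must be non-empty")
  if (is.null(names(cod))) names(cod) <- paste0("coding_", seq_along(cod))
  if (is.null(names(nc))) names(nc) <- paste0("noncoding_", seq_along(nc))
  cod <- cod[!duplicated(unname(cod))]
  nc <- nc[!duplicated(unname(nc))]
  clash <- intersect(unname(cod), unname(nc))
  conflicts <- character(0)
  if (length(clash)) {
    conflicts <- c(names(cod)[cod %in% clash], names(nc)[nc %in% clash])
    warning(length(clash), " sequence(s) labeled both coding and noncoding ",
            "removed: ", paste(utils::head(conflicts, 6), collapse = ", "))
    cod <- cod[!(cod %in% clash)]
    nc <- nc[!(nc %in% clash)]
  }
  if (length(cod) == 0L || length(nc) == 0L)
    stop("a class is empty after deduplication")
  structure(list(id = c(names(cod), names(nc)),
                 sequence = unname(c(cod, nc)),
                 label = rep(c("coding", "noncoding"),
                             c(length(cod), length(nc))),
                 conflicts = conflicts),
            class = "labeled_seqs")
}

#' Hexamer usage log-ratio table
#'
#' Estimates, with add-one smoothing, the frequency of each of the 4096
#' hexamers in the coding and noncoding training sequences and returns the
#' per-hexamer log-ratio log(f_coding / f_noncoding). Coding sequences,
#' through codon-usage bias, occupy a different region of hexamer space
#' than noncoding ones, making the average log-ratio of a query sequence a
#' strong coding-potential feature.
#'
#' @param coding_seqs,noncoding_seqs character vectors of sequences.
#' @return named numeric vector of length 4096.
#' @export
hexamer_table <- function(coding_seqs, noncoding_seqs) {
  count6 <- function(seqs) {
    x <- Biostrings::DNAStringSet(seqs)
    colSums(Biostrings::oligonucleotideFrequency(x, width = 6, step = 1))
  }
  fc <- count6(coding_seqs) + 1
  fn <- count6(noncoding_seqs) + 1
  log(fc / sum(fc)) - log(fn / sum(fn))
}

# Fickett-style positional-bias statistic: for each base, the ratio of the
# maximum to the minimum occupancy over the three codon-frame positions
# (plus one in the denominator). Random sequence scores near 0 on the log
# scale; periodic codon bias pushes it up.
fickett_position_score <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pos <- (seq_along(chars) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- tabulate(pos[chars == b] + 1L, nbins = 3L)
    score <- score + log((max(cnt) + 1) / (min(cnt) + 1))
  }
  score / 4
}

#' Extract coding-potential features from one sequence
#'
#' The feature vector comprises the longest-ORF length and coverage
#' (fraction of the transcript), GC fraction, a Fickett-style positional
#' bias score, the mean hexamer log-ratio under a supplied
#' [hexamer_table()], and the normalized k-mer spectra for k = 1, 2, 3
#' (each block sums to 1).
#'
#' @param sequence nucleotide string over A/C/G/T/N.
#' @param hex_tab hexamer log-ratio table from [hexamer_table()], or `NULL`
#'   to report a zero hexamer bias.
#' @return named numeric vector (fixed order).
#' @export
extract_features <- function(sequence, hex_tab = NULL) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L == 0L || gsub("N", "", sequence, fixed = TRUE) == "")
    stop("sequence is empty or all-N")
  dna <- Biostrings::DNAString(sequence)
  k1 <- Biostrings::oligonucleotideFrequency(dna, 1)
  k2 <- Biostrings::oligonucleotideFrequency(dna, 2)
  k3 <- Biostrings::oligonucleotideFrequency(dna, 3)
  norm <- function(v) if (sum(v) > 0) v / sum(v) else v
  k1 <- norm(k1); k2 <- norm(k2); k3 <- norm(k3)
  orf <- find_longest_orf(sequence)
  hexbias <- 0
  if (!is.null(hex_tab) && L >= 6L) {
    h6 <- Biostrings::oligonucleotideFrequency(dna, 6, step = 1)
    tot <- sum(h6)
    if (tot > 0) hexbias <- sum(h6 * hex_tab[names(h6)]) / tot
  }
  c(orf_length_nt = orf$length_nt,
    orf_coverage = orf$length_nt / L,
    gc_fraction = unname((k1["C"] + k1["G"])),
    fickett_score = fickett_position_score(sequence),
    hexamer_bias = hexbias,
    stats::setNames(k1, paste0("k1_", names(k1))),
    stats::setNames(k2, paste0("k2_", names(k2))),
    stats::setNames(k3, paste0("k3_", names(k3))))
}

# vectorized feature matrix (rows = sequences)
feature_matrix <- function(seqs, hex_tab = NULL) {
  m <- t(vapply(seqs, extract_features, hex_tab = hex_tab,
                FUN.VALUE = numeric(89)))
  rownames(m) <- names(seqs)
  m
}

#' Train the coding-potential random-forest classifier
#'
#' Fits a random forest (500 trees, sqrt(p) candidate features per split)
#' on the extracted feature matrix, with stratified k-fold cross-validation
#' to report held-out precision and recall for the noncoding (lncRNA)
#' class. Tree depth is tuned by out-of-bag error over a small maxnodes
#' grid (unlimited, 256, 64). The hexamer log-ratio table is estimated
#' from the training split only inside each CV fold, and from the full
#' training set for the final refit, so CV metrics are not contaminated.
#'
#' @param training a `labeled_seqs` from [build_training_set()].
#' @param k_folds number of CV folds (default 10).
#' @param seed integer seed controlling fold assignment and forest
#'   randomness.
#' @param n_trees number of trees.
#' @return a `coding_classifier`: the fitted forest, hexamer table,
#'   feature names, per-fold `cv_metrics` (precision/recall/accuracy), the
#'   chosen maxnodes and the seed.
#' @export
train_classifier <- function(training, k_folds = 10L, seed = 1L,
                             n_trees = 500L) {
  lab <- training$label
  if (length(unique(lab)) < 2L)
    stop("training set must contain both classes")
  if (min(table(lab)) < k_folds)
    stop("need at least k_folds = ", k_folds, " records per class")
  seqs <- stats::setNames(training$sequence, training$id)
  set.seed(seed)
  # stratified fold assignment
  fold <- integer(length(lab))
  for (cl in unique(lab)) {
    idx <- which(lab == cl)
    fold[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
  }
  cv <- data.frame(fold = seq_len(k_folds), precision = NA_real_,
                   recall = NA_real_, accuracy = NA_real_)
  for (f in seq_len(k_folds)) {
    tr <- fold != f; te <- !tr
    ht <- hexamer_table(seqs[tr & lab == "coding"],
                        seqs[tr & lab == "noncoding"])
    xtr <- feature_matrix(seqs[tr], ht)
    xte <- feature_matrix(seqs[te], ht)
    fit <- randomForest::randomForest(xtr, factor(lab[tr]),
                                      ntree = n_trees)
    pred <- stats::predict(fit, xte)
    tp <- sum(pred == "noncoding" & lab[te] == "noncoding")
    fp <- sum(pred == "noncoding" & lab[te] == "coding")
    fn <- sum(pred == "coding" & lab[te] == "noncoding")
    cv$precision[f] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    cv$recall[f] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    cv$accuracy[f] <- mean(pred == lab[te])
  }
  # final refit on the full training set; depth grid tuned by OOB error
  ht <- hexamer_table(seqs[lab == "coding"], seqs[lab == "noncoding"])
  x <- feature_matrix(seqs, ht)
  y <- factor(lab)
  grid <- list(unlimited = NULL, mn256 = 256L, mn64 = 64L)
  # a tree cannot have more leaves than training rows
  grid <- grid[vapply(grid, function(mn) is.null(mn) || mn < nrow(x),
                      logical(1))]
  oob <- vapply(grid, function(mn) {
    fit <- randomForest::randomForest(x, y, ntree = n_trees, maxnodes = mn)
    fit$err.rate[n_trees, "OOB"]
  }, numeric(1))
  best <- names(grid)[which.min(oob)]
  model <- randomForest::randomForest(x, y, ntree = n_trees,
                                      maxnodes = grid[[best]])
  structure(list(model = model, hex_tab = ht,
                 feature_names = colnames(x), cv_metrics = cv,
                 maxnodes = grid[[best]], seed = seed),
            class = "coding_classifier")
}

#' Predict coding potential for candidate sequences
#'
#' @param object a `coding_classifier`.
#' @param sequences named character vector (or `DNAStringSet`) of candidate
#'   sequences.
#' @param ... unused.
#' @return data.frame with `id`, `label` (`coding`/`noncoding`),
#'   `p_coding`, `p_noncoding` (summing to 1 per row).
#' @export
predict.coding_classifier <- function(object, sequences, ...) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (length(sequences) == 0L)
    return(data.frame(id = character(0), label = character(0),
                      p_coding = numeric(0), p_noncoding = numeric(0)))
  x <- feature_matrix(sequences, object$hex_tab)
  if (!identical(colnames(x), object$feature_names))
    stop("feature order mismatch between model and candidates")
  prob <- stats::predict(object$model, x, type = "prob")
  data.frame(id = names(sequences),
             label = ifelse(prob[, "noncoding"] >= 0.5,
                            "noncoding", "coding"),
             p_coding = unname(prob[, "coding"]),
             p_noncoding = unname(prob[, "noncoding"]),
             row.names = NULL)
}

#' Predict lncRNAs among triaged candidates
#'
#' Runs the classifier on the candidate transcripts and drops those
#' predicted as mRNA (coding).
#'
#' @param model a `coding_classifier`.
#' @param tx a `transcript_tbl` with sequences attached.
#' @return list: `predictions` (per-candidate data.frame) and `lncrna`
#'   (the subset of `tx` predicted noncoding).
#' @export
predict_lncrna <- function(model, tx) {
  seqs <- stats::setNames(tx$sequence, tx$transcript_id)
  pred <- stats::predict(model, seqs)
  keep <- pred$id[pred$label == "noncoding"]
  list(predictions = pred,
       lncrna = tx[tx$transcript_id %in% keep, , drop = FALSE])
}
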