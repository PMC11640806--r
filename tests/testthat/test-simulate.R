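test_that("configuration invariants are enforced", {
  expect_error(sim_config(class_code_mix = c(u = 0.5, x = 0.2)),
               "sum to 1")
  expect_error(sim_config(n_per_group = 1), "n_per_group")
  expect_error(sim_config(nb_dispersion = 0), "positive")
  expect_error(sim_config(groups = "one"), "two group")
})

test_that("class-code mix and empty configurations behave as forced", {
  cfg <- sim_config(seed = 2, class_code_mix = c(u = 1.0),
                    n_planted_dels = 0, n_cis_pairs = 0,
                    n_trans_pairs = 0)
  ann <- simulate_annotation(cfg)
  expect_true(all(ann$novel$class_code == "u"))
  cfg0 <- sim_config(seed = 2, n_novel_transcripts = 0,
                     frac_novel_coding = 0)
  ann0 <- simulate_annotation(cfg0)
  expect_equal(nrow(ann0$novel), 0L)
  expect_equal(length(ann0$truth$true_class), 0L)
  expect_equal(nrow(ann0$truth$pairs), 0L)
})

test_that("planted cis pairs respect the 20 kb window (interval oracle)", {
  total_checked <- 0
  for (seed in 1:2) {
    cfg <- sim_config(seed = seed, n_chromosomes = 6,
                      n_reference_genes = 600,
                      n_novel_transcripts = 600,
                      frac_novel_coding = 0,
                      n_planted_dels = 500,
                      n_cis_pairs = 500, n_trans_pairs = 100)
    ann <- simulate_annotation(cfg)
    tx <- rbind(as.data.frame(ann$reference), as.data.frame(ann$novel))
    sp_start <- vapply(tx$exon_starts, function(s) s[1], integer(1))
    sp_end <- vapply(tx$exon_ends, function(e) e[length(e)], integer(1))
    names(sp_start) <- names(sp_end) <- tx$transcript_id
    chrom <- setNames(tx$chrom, tx$transcript_id)
    pairs <- ann$truth$pairs
    cis <- pairs[pairs$mode == "cis", ]
    total_checked <- total_checked + nrow(cis)
    for (j in seq_len(nrow(cis))) {
      a <- cis$del_id[j]; b <- paste0(cis$gene_id[j], ".t1")
      expect_equal(chrom[[a]], chrom[[b]])
      gap <- max(0, max(sp_start[[a]], sp_start[[b]]) -
                   min(sp_end[[a]], sp_end[[b]]) - 1)
      expect_lt(gap, 20000)
    }
    trans <- pairs[pairs$mode == "trans", ]
    for (j in seq_len(nrow(trans))) {
      a <- trans$del_id[j]; b <- paste0(trans$gene_id[j], ".t1")
      if (chrom[[a]] == chrom[[b]]) {
        gap <- max(sp_start[[a]], sp_start[[b]]) -
          min(sp_end[[a]], sp_end[[b]]) - 1
        expect_gte(gap, 1e6)
      } else succeed()
    }
  }
  expect_gte(total_checked, 900)  # essentially all planted cis pairs kept
})

test_that("sequences carry the planted ORF contrast and exact lengths", {
  cfg <- sim_config(seed = 4, n_novel_transcripts = 30,
                    frac_novel_coding = 0.5)
  ann <- simulate_annotation(cfg)
  seqs <- simulate_sequences(ann$novel, cfg, ann$truth)
  lens <- transcript_length(ann$novel)
  expect_equal(nchar(seqs), lens[names(seqs)])
  for (id in names(seqs)) {
    orf <- brute_force_orf(seqs[[id]])
    if (ann$truth$true_class[[id]] == "coding")
      expect_gte(orf$length_nt, 300)
    else expect_lt(orf$length_nt, 300)
  }
  # requesting a coding ORF in a too-short transcript fails
  short <- toy_tx("tiny", 250, 2)
  truth <- structure(list(true_class = c(tiny = "coding")),
                     class = "ground_truth")
  expect_error(simulate_sequences(short, cfg, truth), "cannot plant")
})

test_that("identical seeds give identical outputs across all generators", {
  run_all <- function() {
    cfg <- sim_config(seed = 12, n_coding = 15, n_noncoding = 15)
    ann <- simulate_annotation(cfg)
    list(ann = ann,
         seqs = simulate_sequences(ann$novel, cfg, ann$truth),
         corpus = simulate_training_corpus(cfg),
         counts = simulate_counts(cfg, ann$truth),
         hits = simulate_hit_table(ann$novel, ann$truth, cfg),
         terms = simulate_term_map(paste0("G", 1:20), cfg))
  }
  a <- run_all(); b <- run_all()
  expect_identical(a, b)
  # byte-identical FASTA output
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(a$seqs, f1); write_fasta(b$seqs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("NB counts have the planted moments and group-mean ratios", {
  cfg <- sim_config(seed = 9, n_reference_genes = 3,
                    n_novel_transcripts = 0, frac_novel_coding = 0,
                    n_planted_dels = 0, n_cis_pairs = 0,
                    n_trans_pairs = 0, n_per_group = 5000,
                    baseline_log_mean = log(100), baseline_log_sd = 0,
                    nb_dispersion = 0.05)
  truth <- structure(list(true_class = setNames(character(0),
                                                character(0)),
                          true_de = setNames(numeric(0), character(0)),
                          pairs = data.frame(del_id = character(0),
                                             gene_id = character(0),
                                             sign = character(0),
                                             mode = character(0))),
                     class = "ground_truth")
  cnt <- simulate_counts(cfg, truth)
  x <- as.numeric(cnt$counts[1, ])   # 10,000 draws at mu = 100
  se_mean <- sqrt((100 + 0.05 * 100^2) / length(x))
  expect_lt(abs(mean(x) - 100), 3 * se_mean)
  expect_lt(abs(var(x) - 600) / 600, 0.10)
  expect_true(all(cnt$counts >= 0))
  expect_true(is.integer(cnt$counts))
})

test_that("null fold changes centre at zero; planted ones hit their target", {
  cfg <- sim_config(seed = 14, n_reference_genes = 200,
                    n_novel_transcripts = 0, frac_novel_coding = 0,
                    n_planted_dels = 0, n_cis_pairs = 0,
                    n_trans_pairs = 0, n_per_group = 50)
  truth <- structure(list(true_class = setNames(character(0),
                                                character(0)),
                          true_de = setNames(numeric(0), character(0)),
                          pairs = data.frame(del_id = character(0),
                                             gene_id = character(0),
                                             sign = character(0),
                                             mode = character(0))),
                     class = "ground_truth")
  cnt <- simulate_counts(cfg, truth)
  g2 <- cnt$design$group == cfg$groups[2]
  lr <- log2(rowMeans(cnt$counts[, g2]) + 0.5) -
    log2(rowMeans(cnt$counts[, !g2]) + 0.5)
  expect_lt(abs(mean(lr)), 0.05)
  # expected-count matrix encodes the planted ratio exactly
  truth2 <- truth
  truth2$true_de <- c(GENE_0001 = 2.5)
  cnt2 <- simulate_counts(cfg, truth2)
  expect_equal(log2(mean(cnt2$mu["GENE_0001", g2]) /
                      mean(cnt2$mu["GENE_0001", !g2])), 2.5,
               tolerance = 1e-9)
})

test_that("zero-noise planted pair is perfectly correlated", {
  cfg <- sim_config(seed = 16, n_reference_genes = 5,
                    n_novel_transcripts = 2, frac_novel_coding = 0,
                    n_planted_dels = 0, n_cis_pairs = 0,
                    n_trans_pairs = 0, count_noise = "none")
  truth <- structure(
    list(true_class = c(NOVT_0001 = "lncRNA", NOVT_0002 = "lncRNA"),
         true_de = setNames(numeric(0), character(0)),
         pairs = data.frame(del_id = "NOVT_0001", gene_id = "GENE_0001",
                            sign = "positive", mode = "trans")),
    class = "ground_truth")
  cnt <- simulate_counts(cfg, truth)
  logn <- log2(normalize_counts(cnt$counts) + 1)
  r <- cor(logn["NOVT_0001", ], logn["GENE_0001", ])
  expect_equal(r, 1, tolerance = 1e-3)
})
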