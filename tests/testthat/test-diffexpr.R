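test_that("size factors: symmetry, scaling and formula oracle", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("f", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  rownames(m2) <- paste0("f", 1:3)
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(unname(prod(sf)), 1)  # geometric mean 1 for a 1:2 split
  # literal median-of-ratios recomputation on a random matrix
  set.seed(3)
  m3 <- matrix(rnbinom(400, mu = 50, size = 10) + 1L, 50, 8,
               dimnames = list(paste0("f", 1:50), paste0("s", 1:8)))
  sf3 <- size_factors(m3)
  geo <- exp(rowMeans(log(m3)))
  oracle <- apply(m3 / geo, 2, median)
  expect_equal(unname(sf3), unname(oracle), tolerance = 1e-12)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "no feature")
})

test_that("size factors agree with the reference median-of-ratios engine", {
  set.seed(8)
  # odd all-positive feature count: the plain ratio median and the
  # reference engine's exp(median(log ratio)) coincide exactly
  m <- matrix(rnbinom(808, mu = 100, size = 5) + 1L, 101, 8)
  rownames(m) <- paste0("f", 1:101); colnames(m) <- paste0("s", 1:8)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("BH step-up matches the hand-computed case and its properties", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("null features give near-zero log2FC and flat p-values", {
  set.seed(21)
  mu <- matrix(100, 500, 8)
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 20), 500, 8,
                dimnames = list(paste0("f", 1:500), paste0("s", 1:8)))
  des <- data.frame(sample = paste0("s", 1:8),
                    group = rep(c("A", "B"), each = 4))
  res <- nb_wald_test(cnt, des, reference = "A")
  expect_lt(abs(mean(res$log2fc)), 0.05)
  expect_gt(mean(res$p_value), 0.4)  # roughly uniform
  expect_true(all(res$p_adjusted >= res$p_value))
  # all-zero feature flagged with p = 1, lfc = 0
  cnt[1, ] <- 0L
  res0 <- nb_wald_test(cnt, des, reference = "A")
  expect_true(res0$all_zero[1])
  expect_equal(res0$p_value[1], 1)
  expect_equal(res0$log2fc[1], 0)
})

test_that("planted log2FC is recovered with the documented direction", {
  set.seed(33)
  mu <- matrix(100, 200, 8)
  mu[1:50, 5:8] <- 800    # contrast group upregulated, lfc = +3
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 20), 200, 8,
                dimnames = list(paste0("f", 1:200), paste0("s", 1:8)))
  des <- data.frame(sample = paste0("s", 1:8),
                    group = rep(c("CPA", "CPA_TAM"), each = 4))
  res <- call_de(nb_wald_test(cnt, des, reference = "CPA"))
  expect_gt(mean(res$log2fc[1:50]), 2.5)
  expect_gte(mean(res$is_de[1:50]), 0.9)
  expect_equal(sum(res$direction[1:50] == "down"), 0)
  # partition identity up + down = total DE
  expect_equal(sum(res$direction == "up") + sum(res$direction == "down"),
               sum(res$is_de))
})

test_that("DE calling thresholds are strict/non-strict as documented", {
  res <- data.frame(feature_id = c("a", "b", "c"),
                    log2fc = c(2, 1.0, 0.99),
                    p_adjusted = c(0.05, 0.01, 0.001))
  out <- call_de(res)
  expect_false(out$is_de[1])   # padj exactly 0.05 is not DE
  expect_true(out$is_de[2])    # |lfc| exactly 1.0 is DE
  expect_false(out$is_de[3])
  expect_equal(out$direction, c("ns", "up", "ns"))
})

test_that("sample similarity: duplicates at distance 0, variance sums to 1", {
  set.seed(5)
  cnt <- matrix(rnbinom(300, mu = 50, size = 10) + 1L, 100, 3,
                dimnames = list(paste0("f", 1:100), c("a", "b", "c")))
  cnt[, 2] <- cnt[, 1]
  ss <- sample_similarity(cnt)
  expect_equal(ss$dist["a", "b"], 0)
  expect_true(isSymmetric(ss$dist))
  expect_equal(unname(diag(ss$dist)), rep(0, 3))
  expect_lte(sum(ss$var_explained), 1 + 1e-9)
  # hand-computed Euclidean distance on the log scale
  logm <- log2(sweep(cnt, 2, size_factors(cnt), "/") + 1)
  expect_equal(ss$dist["a", "c"],
               sqrt(sum((logm[, "a"] - logm[, "c"])^2)),
               tolerance = 1e-10)
  expect_error(sample_similarity(cnt[, 1:2]), "3 samples")
})

test_that("feature-structure comparison reports mean, SEM and ordering", {
  tx <- toy_tx(c("l1", "l2", "m1", "m2"), c(100, 300, 2000, 4000),
               c(2, 2, 4, 6))
  labels <- c(l1 = "lncRNA", l2 = "lncRNA", m1 = "mRNA", m2 = "mRNA")
  cmp <- compare_feature_structure(tx, labels)
  s <- cmp$summary
  lnc_len <- s[s$class == "lncRNA" & s$metric == "transcript_length", ]
  expect_equal(lnc_len$mean, 200)
  expect_equal(lnc_len$sem, 100)
  mr_len <- s[s$class == "mRNA" & s$metric == "transcript_length", ]
  expect_gt(mr_len$mean, lnc_len$mean)  # planted ordering
  expect_equal(sum(cmp$length_bins$lncRNA), 2)
  expect_error(compare_feature_structure(tx, c(l1 = "lncRNA",
                                               l2 = "lncRNA")),
               "non-empty")
  # degenerate single-member class
  cmp1 <- compare_feature_structure(
    tx[c(1, 3), ], c(l1 = "lncRNA", m1 = "mRNA"))
  one <- cmp1$summary[cmp1$summary$metric == "transcript_length", ]
  expect_true(all(one$sem_degenerate))
  expect_equal(one$sem, c(0, 0))
})
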