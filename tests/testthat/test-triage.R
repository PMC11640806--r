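test_that("transcript container enforces exon-chain invariants", {
  expect_error(transcript_table("t1", "g1", "chr1", "+",
                                list(c(100, 50)), list(c(150, 120))),
               "not sorted")
  expect_error(transcript_table("t1", "g1", "chr1", "+",
                                list(c(100, 140)), list(c(150, 200))),
               "overlapping")
  expect_error(transcript_table("t1", "g1", "chr1", "+",
                                list(100), list(50)), "end < start")
  tx <- toy_tx("t1", 300, 2)
  expect_equal(unname(transcript_length(tx)), 300L)
  expect_error(attach_sequences(tx, c(t1 = "ACGT")), "length")
})

test_that("class-code filter keeps the allowed set and warns on unknowns", {
  tx <- toy_tx(paste0("t", 1:10), 300, 2,
               class_codes = c("u", "=", "x", "c", "i", "o", "j", "=",
                               "u", "e"))
  kept <- filter_by_class_code(tx)
  # independent membership oracle
  expect_setequal(kept$transcript_id,
                  tx$transcript_id[tx$class_code %in%
                                     c("x", "o", "i", "u", "j")])
  expect_equal(kept$transcript_id,
               intersect(tx$transcript_id, kept$transcript_id)) # order
  expect_warning(filter_by_class_code(toy_tx("q1", 300, 2, "?")),
                 "unknown class code")
  expect_equal(nrow(suppressWarnings(
    filter_by_class_code(toy_tx("q1", 300, 2, "?")))), 0L)
})

test_that("structural filter applies both thresholds at the boundary", {
  tx <- toy_tx(paste0("t", 1:4), c(199, 200, 5000, 250),
               c(3, 2, 1, 2))
  kept <- filter_by_structure(tx)
  expect_setequal(kept$transcript_id, c("t2", "t4"))
  # 199 nt fails even with many exons; 5 kb single-exon fails
  expect_false("t1" %in% kept$transcript_id)
  expect_false("t3" %in% kept$transcript_id)
})

test_that("longest-ORF scanner matches hand-checked cases", {
  r <- find_longest_orf("ATGAAATAA")
  expect_equal(r$length_nt, 6L)
  expect_equal(r$start_offset, 0L)
  expect_true(r$has_stop)
  expect_equal(find_longest_orf("CCCCCC")$length_nt, 0L)
  expect_equal(find_longest_orf("")$length_nt, 0L)
  # N inside a codon terminates the run without being a stop
  r <- find_longest_orf("ATGAAANAAAAA")
  expect_equal(r$length_nt, 6L)
  expect_false(r$has_stop)
  # open-ended ORF without a stop
  r <- find_longest_orf("ATGAAAAAA")
  expect_equal(r$length_nt, 9L)
  expect_false(r$has_stop)
})

test_that("longest-ORF scanner equals the exhaustive oracle on random input", {
  set.seed(42)
  for (i in 1:1000) {
    len <- sample(3:500, 1)
    s <- paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    got <- find_longest_orf(s)
    want <- brute_force_orf(s)
    expect_identical(got, want, label = paste("seq", i))
  }
})

test_that("ORF filter boundary and direction behave as documented", {
  sho <- paste0("ATG", strrep("AAA", 98), "TAA")   # ORF = 297 nt
  bnd <- paste0("ATG", strrep("AAA", 99), "TAA")   # ORF = 300 nt
  tx <- toy_tx(c("short", "long"), nchar(c(sho, bnd)), 2,
               sequences = c(sho, bnd))
  expect_equal(filter_by_orf(tx)$transcript_id, "short")
  expect_equal(filter_by_orf(tx, mode = "drop_short")$transcript_id,
               "long")
  expect_lt(find_longest_orf(sho)$length_nt, 300)
  expect_error(filter_by_orf(toy_tx("t1", 300, 2)), "missing sequence")
})

test_that("triage cascade tallies match independent per-rule recomputation", {
  set.seed(99)
  n <- 100
  codes <- sample(c("u", "x", "i", "j", "o", "=", "c"), n, replace = TRUE)
  lens <- sample(c(150, 199, 200, 400, 900), n, replace = TRUE)
  nex <- sample(1:4, n, replace = TRUE)
  lens <- pmax(lens, nex * 10L)
  tx <- toy_tx(paste0("t", 1:n), lens, nex, class_codes = codes)
  seqs <- vapply(transcript_length(tx), function(L) {
    if (runif(1) < 0.3 && L >= 320)
      paste0("ATG", paste(sample(c("AAA", "GAA", "CAA"), 105,
                                 replace = TRUE), collapse = ""),
             "TAA", random_seq(L - 321))
    else random_seq(L)
  }, "")
  tx <- attach_sequences(tx, setNames(seqs, tx$transcript_id))
  rep <- run_triage(tx)
  # oracle tallies by direct set logic
  pass1 <- codes %in% c("x", "o", "i", "u", "j")
  pass2 <- pass1 & lens >= 200 & nex >= 2
  orf_len <- vapply(seqs, function(s) brute_force_orf(s)$length_nt,
                    integer(1))
  pass3 <- pass2 & orf_len < 300
  expect_equal(unname(rep$counts[["dropped_class_code"]]), sum(!pass1))
  expect_equal(unname(rep$counts[["dropped_structure"]]),
               sum(pass1 & !pass2))
  expect_equal(unname(rep$counts[["dropped_orf"]]), sum(pass2 & !pass3))
  expect_equal(unname(rep$counts[["retained"]]), sum(pass3))
  expect_equal(sum(rep$counts[c("dropped_class_code", "dropped_structure",
                                "dropped_orf", "retained")]),
               unname(rep$counts[["input"]]))
  # set-level order invariance
  perm <- sample(n)
  rep2 <- run_triage(tx[perm, ])
  expect_setequal(rep2$retained$transcript_id,
                  rep$retained$transcript_id)
  # filters shrink monotonically and are idempotent
  s1 <- filter_by_class_code(tx)
  expect_true(all(s1$transcript_id %in% tx$transcript_id))
  expect_identical(filter_by_class_code(s1), s1)
  s2 <- filter_by_structure(s1)
  expect_identical(filter_by_structure(s2), s2)
})

test_that("triage handles empty and all-pass inputs", {
  tx <- toy_tx(character(0), integer(0), integer(0))
  rep <- run_triage(tx[0, ])
  expect_true(all(rep$counts == 0))
  ok <- toy_tx(c("a", "b"), 400, 2, class_codes = "u",
               sequences = c(random_seq(400), random_seq(400)))
  # regenerate until no long ORF (rare at 400 nt)
  set.seed(1)
  seqs <- vapply(c(400L, 400L), function(L) {
    repeat {
      s <- random_seq(L)
      if (brute_force_orf(s)$length_nt < 300) return(s)
    }
  }, "")
  ok <- attach_sequences(ok, setNames(seqs, ok$transcript_id))
  rep <- run_triage(ok)
  expect_equal(unname(rep$counts[["retained"]]), 2L)
  expect_setequal(rep$retained$transcript_id, ok$transcript_id)
})
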