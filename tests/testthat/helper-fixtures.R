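# Shared fixture builders: everything is generated in code at test time.

# single-exon-chain toy transcript table
toy_tx <- function(ids, lengths, n_exons, class_codes = "u",
                   chrom = "chr1", sequences = NA_character_) {
  n <- length(ids)
  n_exons <- rep_len(n_exons, n)
  lengths <- rep_len(lengths, n)
  starts <- vector("list", n); ends <- vector("list", n)
  pos <- 1000L
  for (i in seq_len(n)) {
    per <- diff(floor(seq(0, lengths[i], length.out = n_exons[i] + 1L)))
    s <- integer(n_exons[i]); e <- integer(n_exons[i])
    q <- pos
    for (j in seq_len(n_exons[i])) {
      s[j] <- q; e[j] <- q + per[j] - 1L
      q <- e[j] + 500L
    }
    starts[[i]] <- s; ends[[i]] <- e
    pos <- q + 10000L
  }
  transcript_table(ids, sprintf("%s_g", ids), rep_len(chrom, n),
                   rep_len("+", n), starts, ends,
                   class_code = rep_len(class_codes, n),
                   sequence = rep_len(sequences, n))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# independent exhaustive ORF oracle: every (start, frame) pair scanned
brute_force_orf <- function(sequence) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  stops <- c("TAA", "TAG", "TGA")
  best <- list(start_offset = NA_integer_, length_nt = 0L,
               frame = NA_integer_, has_stop = FALSE)
  if (L < 3L) return(best)
  for (s in 0:(L - 3L)) {
    if (substr(sequence, s + 1L, s + 3L) != "ATG") next
    len <- 0L; stopped <- FALSE
    pos <- s
    while (pos + 3L <= L) {
      codon <- substr(sequence, pos + 1L, pos + 3L)
      if (grepl("N", codon, fixed = TRUE)) break
      if (codon %in% stops) { stopped <- TRUE; break }
      len <- len + 3L
      pos <- pos + 3L
    }
    frame <- s %% 3L
    if (len > best$length_nt ||
        (len == best$length_nt && len > 0L &&
         (s < best$start_offset ||
          (s == best$start_offset && frame < best$frame)))) {
      best <- list(start_offset = s, length_nt = len, frame = frame,
                   has_stop = stopped)
    }
  }
  best
}

# independent step-up BH implementation for cross-checking
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# exhaustive hypergeometric upper tail by direct combinatorial sum
hyper_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
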