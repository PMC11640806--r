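Package: lncscreen
Title: Long Noncoding RNA Discovery and Regulatory Target Inference from
    Assembled Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens assembled transcripts for candidate long noncoding RNAs
    (lncRNAs) and infers their regulatory targets in a two-group RNA-seq
    design. The pipeline triages transcripts by gffcompare class code,
    length, exon count and longest open reading frame; classifies coding
    potential with a random-forest model trained on sequence features
    (ORF statistics, GC content, Fickett-style positional bias, hexamer
    usage, k-mer spectra); triages candidates against tabular homology
    hits into coding, known-lncRNA and no-match groups; calls
    differentially expressed lncRNAs and genes with a negative-binomial
    Wald test on median-of-ratios normalized counts; assigns cis
    (< 20 kb) and trans targets by expression correlation; and performs
    hypergeometric over-representation analysis against a supplied term
    map. A synthetic-data module generates annotations, sequences, count
    matrices, homology tables and term maps with planted ground truth so
    the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
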