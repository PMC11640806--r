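---
title: "lncscreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncscreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lncscreen implements a complete desk-scale pipeline for discovering long
noncoding RNAs (lncRNAs) in an assembled transcriptome and inferring
their regulatory targets in a two-group RNA-seq comparison (for example
a treated versus control design with four biological replicates per
group). This vignette explains the statistical machinery behind each
stage, the parameters that matter, and the choices made where the
methodology was genuinely open.

## Candidate triage

Novel-transcript discovery starts from a gffcompare-annotated GTF.
Three filters run in a fixed order:

1. **Class code.** Transcripts whose relation to the reference is
   antisense ("x"), generic same-locus overlap ("o"), intronic ("i"),
   intergenic ("u") or a novel isoform ("j") are retained; exact and
   contained matches of known transcripts are discarded. Unknown class
   codes are dropped with a warning rather than silently retained.
2. **Structure.** Transcripts shorter than 200 nt or with fewer than
   two exons are removed. 200 nt is the defining length floor for
   lncRNAs; mono-exonic assemblies are heavily contaminated by
   fragments and are excluded for the same reason most lncRNA
   pipelines exclude them. Both thresholds are inclusive on the
   retained side (exactly 200 nt with exactly 2 exons survives).
3. **Open reading frame.** The longest ORF is found by scanning the
   three forward frames of the given strand — assembled transcripts are
   already stranded, so the reverse complement is deliberately not
   scanned. An ORF is an ATG-initiated codon run; its length counts the
   ATG through the last codon before the stop, excluding the stop
   itself, so the 300 nt threshold corresponds exactly to 100 amino
   acids. A codon containing N terminates a run without counting as a
   stop, and a run may end at the sequence edge (reported with
   `has_stop = FALSE`). Ties are broken toward the smallest start
   offset, then the smallest frame. By default transcripts whose
   longest ORF is **at least** 300 nt are dropped — they have
   substantial coding capacity and are not lncRNA candidates. The
   inverted direction (retaining long-ORF transcripts) is available as
   `mode = "drop_short"` for users who want to reproduce a
   coding-transcript selection; keeping candidates with short ORFs is
   the only direction consistent with lncRNA discovery, which is why it
   is the default.

Each filter is a pure subset operation: output is always a subset of
input, filters are idempotent, and the per-transcript statuses
(`retained`, `dropped_class_code`, `dropped_structure`, `dropped_orf`)
partition the input, so the triage funnel can be reconstructed exactly
from the report.

## Coding-potential classification

Candidates that survive triage are classified as mRNA-like or
lncRNA-like by a random forest trained on labeled sequences. The
training corpus is deduplicated first: identical nucleotide sequences
collapse to a single record (first identifier wins), and a sequence
that appears under *both* labels is removed entirely, since it carries
no usable signal and would otherwise bias the error estimate.

The feature set is fixed and documented rather than delegated to an
external extractor:

* longest-ORF length and coverage (ORF length / transcript length);
* GC fraction;
* a Fickett-style positional-bias score — for each base, the log ratio
  of its maximum to minimum occupancy over the three codon-frame
  positions, averaged over the four bases. Random sequence scores near
  zero; periodic codon structure pushes it up;
* a hexamer-usage bias: the mean log-ratio of coding versus noncoding
  hexamer frequencies under a table estimated from the training set
  with add-one smoothing. No external codon table is used, which keeps
  the package download-free and organism-agnostic;
* the full normalized k-mer spectra for k = 1, 2, 3 (84 features, each
  block summing to one).

Training uses stratified 10-fold cross-validation; the hexamer table is
re-estimated inside each fold from the training split only, so the
reported per-fold precision and recall (for the lncRNA class) are not
contaminated by the held-out sequences. The final model is refit on all
training data with 500 trees and sqrt(p) candidate features per split;
tree depth is tuned by out-of-bag error over a small maxnodes grid
(unlimited, 256, 64). Training and prediction are deterministic under
the supplied seed.

## Homology triage

Predicted lncRNAs are screened against a tabular nucleotide-homology
hit file (the standard 12-column tabular alignment format plus a
`subject_type` column). A hit is significant when its e-value is at
most 1e-5 — the comparison is inclusive, and the 1e-5 boundary is
tested explicitly. Candidates fall into three groups: (1) significant
match to a protein-coding gene or other non-lncRNA transcript —
excluded; (2) significant match to a known lncRNA — retained as a
known lncRNA; (3) no significant match — retained as a novel lncRNA.
When one candidate has significant hits of conflicting types, the
coding evidence dominates and the candidate is excluded; this is the
conservative resolution of a case the methodology leaves open. The
three groups always partition the candidate set.

## Differential expression

The two-group test is a negative-binomial Wald test implemented in the
package:

* **Normalization** is median-of-ratios: for each feature positive in
  every sample, form the ratio of its count to its geometric mean
  across samples; the per-sample size factor is the median of those
  ratios.
* **Dispersion** is estimated per feature by method of moments on the
  normalized counts, using the pooled within-group variance so the
  group effect does not inflate it, floored at 1e-8, then shrunk
  halfway (on the arithmetic scale) toward a least-squares trend
  alpha(mu) = a0 + a1/mu fitted across features. The shrinkage pools
  information across features, which is what makes the test usable at
  n = 4 per group; it is a deliberate, documented simplification of
  the empirical-Bayes machinery in the standard engines.
* **Fold change** is the log2 ratio of group means of normalized
  counts, with a pseudo-count of 0.5 added to both means so groups
  with zero counts give finite estimates; the standard error follows
  from the NB variance (mu + alpha mu^2) by the delta method, and
  log2FC/SE is referred to a standard normal, two-sided.
* **Multiple testing** is Benjamini–Hochberg step-up, implemented
  directly and cross-checked against an independent implementation in
  the tests. The adjustment procedure is BH because that is the
  default of the engine this stage mirrors.
* **Calling**: a feature is differentially expressed iff adjusted
  p < 0.05 (strict) and |log2FC| >= 1.0 (inclusive). Both boundary
  behaviours are pinned by tests. Positive log2FC means higher
  expression in the contrast group.

On the simulation this package ships (2,000 features, mu = 100,
alpha = 0.05, 4 + 4 samples, 20 seeds) the test's empirical type-I
error at nominal 0.05 is about 0.05–0.06, and planted |log2FC| = 3
features are recovered with sensitivity above 0.99 at an empirical FDR
below 0.01 — these numbers are recomputed, not quoted, by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.

All-zero features are reported with log2FC 0 and p 1 and flagged
rather than dropped, so result tables stay aligned with the input.

Sample-level summaries (PCA via singular value decomposition of the
centered sample matrix, and the Euclidean distance matrix) are computed
on log2(normalized count + 1). The structural comparison of lncRNA
versus mRNA reports per-class mean and SEM of transcript length, exon
length and exon number with the conventional bins (<1500, 1500–3000,
>3000 nt; <=3, 4–10, >10 exons); a single-member class reports SEM 0
with an explicit degeneracy flag.

## Cis and trans target inference

Each differentially expressed lncRNA (DEL) is correlated against each
differentially expressed gene (DEG) across all samples of both groups
pooled, on the log2(normalized count + 1) scale — co-expression is
only meaningful on the pooled profile. The statistic is the sample
Pearson r with the exact t-based p-value on n − 2 degrees of freedom.
A pair is retained when |r| >= 0.90 and p < 0.01.

Two notes on these thresholds. First, a squared correlation cannot be
negative, so a selection rule stated in terms of "R² >= 0.90 or
R² <= −0.90" can only mean the signed coefficient; the package
implements |r| >= 0.90 and keeps the sign (positive/negative) as a
pair attribute. Second, the p cutoff is exposed as configuration
(`trans_p_max`) with default 0.01, the stricter of the two values in
circulation for this screen; 0.05 is a one-line change.

Retained pairs are then split by genomic proximity: a pair is **cis**
iff both features lie on the same chromosome and the gap between their
transcript spans (first exon start to last exon end; 0 when the spans
overlap; strand ignored) is strictly below 20,000 bp; every other pair
is **trans**. The distance anchor (span gap rather than TSS distance)
is a package choice, documented because the convention varies across
studies; the 19,999/20,000 boundary is pinned by tests. Reassignment
conserves the pair count, and DELs with at least one cis and one trans
pair are reported as dual-mode — the pattern of locally acting lncRNAs
that also reach distant loci.

Zero-variance expression vectors make r undefined; such features are
skipped with a warning rather than given an arbitrary value.

## Enrichment

Over-representation uses the exact hypergeometric upper tail
P(X >= k), computed in log space with `lchoose` and log-sum-exp so it
is stable for large universes, and verified against exhaustive
enumeration for every feasible configuration with universes up to 60.
The term map is an input file (gene, term, name, namespace): no live
ontology access. The universe is the annotated gene set, intersected
with the expressed genes when supplied — the default behaviour of the
standard enrichment engines; terms smaller than `min_term_size`
(default 3) are not tested. Adjustment is BH across the tested terms
and the enrichment call uses an inclusive cutoff (adjusted p <= 0.05),
intentionally different from the strict inequality used for DE calling
— the two stages keep the conventions of the tools they mirror.

## The synthetic-data module

The generators exist so that every stage has planted, recoverable
truth. Their defaults define the simulated study conditions and are
not tuning knobs:

* two groups ("CPA", "CPA_TAM") with **4 replicates per group**;
* NB counts with dispersion **alpha = 0.05** and log-normal baselines
  (median ~150 counts), typical of bulk RNA-seq at moderate depth;
  sequencing depth itself is a free parameter of the design and is
  left implicit in the baselines;
* planted differential features at **|log2FC| = 3**, matching the
  magnitude of the strongest differential lncRNAs such a two-group
  contrast typically yields;
* novel transcripts dominated by intergenic ("u") class codes, with an
  exact-match fraction included so the class-code filter has work to
  do; planted DELs are forced to "u" so they survive triage;
* coding sequences carry an in-frame planted ORF >= 300 nt drawn from
  a synthetic biased codon table (no organism's real table, keeping
  the package download-free); noncoding sequences are uniform-random
  nucleotides whose longest ORF is verifiably < 300 nt — when a random
  draw contains a long ORF it is truncated by an in-frame stop, so the
  guarantee is constructive;
* pair correlations are planted through a per-DEL Gaussian latent
  factor (sd 1.0 on the natural-log scale) added to both members of a
  pair, sign-flipped for negative pairs; at the default settings this
  dominates the NB noise and yields |r| >= 0.9 in expectation. The
  planted fold change of a paired gene follows its DEL's fold change
  (flipped for negative pairs) so the group-mean step reinforces
  rather than cancels the latent correlation. Negative pairs slightly
  outnumber positive ones (60/40), as is typical of lncRNA-target
  networks;
* cis pairs are placed with a span gap drawn below 20 kb on the same
  chromosome; trans pairs are placed on a different chromosome.

A separate noise-free fixture (`make_pair_fixture()`) orthogonalizes
the latent profiles, so within-pair correlations are exactly +/-1 and
all other DEL–DEG correlations are exactly 0 for *any* seed; its
annotation plants the 19,999 bp (cis) and 20,000 bp (trans) boundary
distances. This is the fixture on which cis/trans recovery is required
to be exact.

What the simulation does **not** emulate: positional read coverage,
GC or length bias, isoform ambiguity, batch effects, outlier samples,
and real hexamer statistics of any genome. Passing the planted-truth
tests therefore demonstrates that the algorithms are implemented
correctly, not that the pipeline's biological error rates on real data
match the simulated ones.

## Numerical and degenerate-input choices

* Coordinates are 1-based closed intervals (GTF convention)
  everywhere; conversions happen only inside the I/O layer.
* `size_factors()` errors when no feature is positive in all samples,
  with a hint to filter first.
* Dispersion floor 1e-8; trend coefficients clamped positive.
* The hypergeometric tail clamps at 1 against accumulated rounding.
* BH rejects p-values outside [0, 1] rather than clipping.
* Problem sizes used by the shipped verification runs: 1,000 random
  sequences for the ORF oracle; a 400-sequence training corpus for the
  classifier; 2,000 features x 20 seeds for DE calibration; a
  40-transcript synthetic genome for the end-to-end run. These sizes
  give stable pass/fail behaviour at desk scale while keeping a full
  run in minutes.

## Known limitations

* The DE engine omits the reference engines' outlier handling (Cook's
  distance) and independent filtering, and supports exactly two
  groups; its dispersion shrinkage is method-of-moments plus a
  parametric trend, not empirical Bayes.
* ORF scanning is forward-strand only, by design.
* The homology stage consumes precomputed hits; it does not run an
  aligner, and the mapping of database subjects to
  protein-coding/non-lncRNA/lncRNA categories is the caller's
  responsibility.
* Enrichment results are only as meaningful as the supplied term map;
  the bundled generator produces a synthetic map for testing, not a
  biological one.
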