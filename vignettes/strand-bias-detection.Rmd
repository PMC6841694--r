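---
title: "Detecting opposite-strand bias in unstranded RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting opposite-strand bias in unstranded RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandsense)
```

# The quantity being estimated

An unstranded RNA-seq library cannot distinguish a read sampled from a
gene's own transcripts from a read sampled from transcription on the
opposite genomic strand at the same locus. When a gene overlaps the exons
of an antisense gene, or lies within a short distance of a highly
expressed gene whose nascent transcription runs past its annotated end,
its unstranded count absorbs those foreign reads. strandsense estimates,
per gene, how likely that absorption is large enough to matter — defined
as a more than two-fold gap between what a stranded and an unstranded
protocol would have counted in the part of the gene shared by both
(its *unique* exonic region).

# Counting semantics

All counting is exon-union, union-mode: a gene's feature is the union of
its transcripts' exons, a read (or, for paired data, the pooled aligned
blocks of a fragment) supports a gene when at least one aligned base
overlaps that union. The six per-gene tallies are evaluated
independently per read:

* `n_ust` counts the read for **every** gene whose exon union it
  touches, strand ignored. It is used only as a within-gene expression
  proxy and never summed across genes, which is why multi-assignment is
  acceptable here.
* `n_ustno` counts the read only when it touches exactly one gene's exon
  union; reads touching two or more are ambiguous and dropped. The
  per-gene total therefore reflects the gene's unique region.
* `n_st` is `n_ust` restricted to genes matching the read's inferred
  strand (dUTP conventions: under `R` the first mate aligns opposite to
  the gene; under `F`, on it).
* `n_stno` is the same-strand **subset** of the gene's `n_ustno` reads.
  Defining it as a subset (rather than re-running the ambiguity rule
  among same-strand genes) guarantees `n_stno <= n_ustno` per gene and
  makes the two unique-region counts refer to the identical reads, so
  `log2(n_ustno / n_stno)` is a non-negative, directly interpretable
  measure of opposite-strand contamination. The alternative definition
  would let an antisense read in an exon-overlap region increment
  `n_stno` without incrementing `n_ustno`, breaking both properties.
* `n_jctn` counts reads with at least one spliced-alignment gap (CIGAR
  `N`) exactly matching an annotated junction of the gene, among the
  reads already counted in its `n_ust`. Exact coordinate equality is
  required; novel junctions are deliberately ignored because the metric
  is defined over *known* junctions, which are strand-attributable.
* `n_intr` counts reads overlapping the gene's introns while touching
  **no** gene's exon union. Excluding any exonic contact keeps the
  metric a measure of intronic signal (nascent RNA or antisense
  carry-over) rather than of mis-annotated exon boundaries.

Alignment filters: secondary, supplementary and duplicate records are
skipped, as are records below `mapq_min` (default 10, a conventional
uniqueness cutoff for spliced aligners; configurable). Reads on
chromosomes absent from the database are skipped and reported in a
diagnostics counter rather than failing the run.

Coordinates are handled throughout as 1-based closed intervals — the
native convention of the GenomicRanges stack the package is built on —
and a splice junction is identified by its intron interval
`[donor_end + 1, acceptor_start - 1]`. GTF input is already 1-based, so
no conversion happens at any boundary.

# Expected junction-read probability

The junction log-ratio metric needs, per gene, the probability that a
read would span an annotated junction *if* the gene's reads came from
its own transcripts. This is computed by exact enumeration, not
sampling, under two assumptions:

1. isoforms of a gene are present in equal molar amounts;
2. coverage is uniform along each transcript (every placement of a read
   on a molecule is equally likely).

For a single-end read of length $R$ on an isoform of spliced length $L$
there are $L - R + 1$ placements ($1$ when $L \le R$: the read covers
the whole molecule). A placement spans a junction when it has at least
`min_overhang` aligned bases on both sides of an isoform-internal exon
boundary; the count of spanning placements is the length of a union of
integer intervals, computed exactly. Placements are pooled across
isoforms — each molecule contributes reads in proportion to its number
of placements, which is precisely equal-molar weighting under uniform
fragmentation — and `p_expected` is pooled spanning placements over
pooled placements. The alternative weighting (equal *read* shares per
isoform) would overweight short isoforms; molar pooling matches how the
read simulator, and a sequencer, actually sample molecules.

`min_overhang` defaults to 8 bases, mirroring the splice-junction
overhang a typical spliced aligner requires before it will emit a gapped
alignment: a simulated read is only counted as junction-spanning if an
aligner would have split it. For paired-end configurations both mates
are tested (a junction inside the mate overlap of short fragments is
counted once), and a fragment-length mixture pools placements over
lengths with the supplied weights.

# From metrics to confidence scores

Features are computed from strand-blind counts only, so they are
available for genuinely unstranded data:

* `junction_log_ratio = log2((n_jctn + 1) / (p_expected * n_ust + 1))`
* `exon_intron_log_ratio = log2(((n_ustno + 1) / nonoverlap_len) /
  ((n_intr + 1) / intron_len))`
* `neighbor_expression = max over neighbors of n_ust / exonic_len`
* `overlap_fraction = 1 - nonoverlap_len / exonic_len`

The pseudocount of one read is applied to every tally before forming
ratios: junction counts of zero are the *typical* case for affected
genes, so unsmoothed ratios would be undefined exactly where the signal
is strongest. Lengths are floored at 1 bp in the density denominators so
that fully overlapped genes (unique length zero) and junction-bearing
genes whose isoforms tile the span without gaps (intron length zero)
yield finite features instead of errors; both tallies are structurally
zero or near-zero in those cases, so the floor only prevents 0/0.

Neighbors are genes (either strand) whose *span* lies within 2,000 bp of
the gene's span, threshold inclusive, overlap counting as distance zero.
The span (rather than the exon union) is the anchor because carry-over
originates from transcription across the whole locus, introns included.
Neighbor expression is normalized by exonic length — the length over
which `n_ust` is collected — rather than span length.

Monoexonic genes have no junctions and no introns, so the first two
features are undefined for them; they are classified from the last two
alone. Two separate `rpart` classification trees are fitted: depth at
most 5 for multiexonic genes (four features) and at most 3 for
monoexonic genes (two features) — one more than the number of features
in each case. Because affected genes are a small minority (about a tenth
of detectable genes), training instances are class-balance weighted by
default; this stabilizes the leaf class fractions, which are used
directly as `p_affected`. `confidence = 1 - p_affected`. Trees are
grown with complexity penalty zero so that depth is the binding
constraint, with the default minimum split size of 20 instances guarding
against leaves fitted to a handful of genes.

Labels for training come from stranded libraries:
`log2((n_ustno + 1) / (n_stno + 1)) > 1` among genes with unstranded TPM
above 1. The TPM for the unique-region counts uses the unique-region
length (the length over which those reads were collected); full exonic
length is used for the other count types. Only detectable genes enter
training — undetectable genes have uninformative ratios pinned to zero
by the pseudocount — while at prediction time every gene with at least
one read is scored and genes with `n_ust = 0` are reported with `NA`
confidence.

Determinism is treated as a contract: database construction, counting,
training (given a seed and instance order) and prediction are all
reproducible to the byte, and the model strips session-dependent
environments before serialization so that retraining writes an identical
file.

# What the synthetic generator emulates

The generator exists so that every stage is testable against known
ground truth without external data. It emulates the conditions under
which opposite-strand bias arises and is studied:

* a gene landscape mixing monoexonic (35%) and multiexonic genes with up
  to two isoforms, always containing an antisense exon-overlap pair, a
  pair gapped under 2,000 bp and a pair gapped over 2,000 bp;
* single-end 50 bp reads from a dUTP reverse-stranded protocol (the
  configuration of the stranded corpora this class of method is trained
  on), drawn uniformly over placements per molecule — exactly the two
  assumptions of the junction-probability model — with spliced reads
  carrying `N` gaps matching annotated junctions and sub-overhang
  junction crossings emitted soft-clipped, as an aligner would report
  them;
* carry-over planted as unspliced reads on the source gene's strand
  placed uniformly over the target gene's span, at a configurable
  multiple of the source's read count, with sources up-weighted and
  targets down-weighted in expression;
* a low rate (3%) of same-strand unspliced nascent-background reads per
  gene, so regular genes have finite exonic/intronic density ratios;
* a 15 pseudo-cell-type corpus sharing a base expression profile and a
  core set of carry-over pairs (covering both monoexonic and multiexonic
  targets) plus type-specific pairs, supporting the
  train-on-14/hold-out-1 evaluation design.

Ground truth records every read's source gene and strand, and the
planted stranded/unstranded unique-region counts are recomputed by an
interval replay that is independent of the BAM writing and parsing path.

The generator does **not** emulate sequencing errors or indels (counting
is CIGAR-driven, so base errors would not change the tested surface),
GC or positional coverage bias, fragment-length variation in single-end
mode, multimapping, or annotation incompleteness. Consequently, passing
tests demonstrate correctness of the counting semantics, the enumeration
and the learning machinery under the stated model — not robustness to
coverage bias or annotation error in real libraries, where junction
probabilities are known to correlate with observation imperfectly.

# Problem sizes and numerical checks

The test suite and the acceptance script run entirely on generated data
chosen to keep a full run within a few minutes on one CPU while leaving
the statistics well-resolved: counting fixtures of 20 genes and at least
10,000 reads (five seeds) verified read-for-read against an independent
per-base brute-force classifier; junction-probability checks against an
exhaustive per-placement oracle on 50 random gene models plus
hand-enumerable two-exon cases (49/151 and 35/151 for a 50 bp read over
100+100 bp exons at overhangs 1 and 8); a concordance fixture of
10,000 reads per gene where empirical junction frequencies must sit
within three binomial standard errors of the enumeration; and the
15-type corpus (60 genes, 12,000 reads per type) for the held-out
classification AUC. Degenerate inputs are exercised explicitly: empty
BAMs, transcripts shorter than the read length (a single whole-molecule
placement), monoexonic genes, fully overlapped genes, all-zero counts
(TPM defined as zero rather than 0/0), and unstranded libraries passed
where stranded ones are required (an error, never a silent guess).

# Known limitations

* The confidence score is a leaf class fraction, not a calibrated
  probability; it ranks genes well but its absolute scale depends on the
  training corpus.
* A model trained on synthetic fixtures (`default_model()`) transfers
  the *logic* of the metrics but not the noise structure of a real
  tissue; training on matched stranded data with `run_train()` is
  preferable whenever such data exist.
* Monoexonic genes are classified from two weak features only; their
  scores are substantially less reliable than multiexonic ones, which
  mirrors the intrinsic information gap rather than an implementation
  limit.
* Junction counts exported for bias-robust downstream analysis are a
  small fraction of total reads, so tests based on them lose power for
  short reads; they become more useful as read length grows.
* Annotations containing very rare transcript models dilute the expected
  junction probability (equal-molar pooling weights every isoform); when
  the annotation provides a confidence tag, building the database with
  `transcript_tag = "basic"` is recommended.
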