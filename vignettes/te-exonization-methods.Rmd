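---
title: "Methods: quantifying transposable-element exonization and its epigenetic correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transposable-element exonization and its epigenetic correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teexon)
```

## The question

Transposable elements (TEs) cover roughly half of the human genome, and a
recurring observation in transcriptomics is that assembled transcripts —
especially those absent from reference gene catalogs — borrow coding
sequence from TE insertions ("exonization"). `teexon` implements a
complete, testable pipeline for quantifying this phenomenon from standard
files: how many exons and transcripts overlap repeat annotation, whether
first exons (and hence transcription start sites) are preferentially
TE-derived, which TE families contribute most once genomic abundance is
accounted for, whether exonization levels track element age, and whether
the expression of TE-derived exons covaries with epigenetic activity marks
(histone modifications, DNaseI hypersensitivity, CAGE clusters).

The package deliberately starts *after* read alignment and transcript
assembly: its inputs are assembled gene models (GTF plus an FPKM table),
RepeatMasker annotation, and peak/cluster calls in BED. Producing those
inputs is the job of established aligner/assembler stacks and is out of
scope here.

## Coordinates and co-location

Everything inside the package uses 0-based half-open intervals. GTF
(1-based closed) is converted on read and write; BED-family formats are
used natively. A single convention eliminates off-by-one drift, and the
half-open rule gives an unambiguous overlap predicate:
`max(starts) < min(ends)` — adjacent intervals never overlap, one shared
base always does.

Co-location is *any overlap*: an exon is TE-derived as soon as one base of
it lies inside a repeat. There is no minimum overlap fraction and strand
is ignored for exon/TE and exon/signal queries (a strand-matched query is
available as a flag). The exon interval itself is the unit of
classification — no CDS sub-interval is carved out, so "exon" and "coding
sequence" are interchangeable here. Overlap queries run through
GenomicRanges, and the test suite holds them to exact agreement with a
brute-force all-pairs scan.

Repeat families are grouped from the RepeatMasker class/family string by
prefix: `SINE/Alu`, `SINE/MIR`, `LINE/L1`, `LINE/L2`, `LTR*`, `DNA*`, and
everything else as `other`. Divergence is stored per-mille (millidiv) in
both supported dialects; the `.out` dialect's percent column is multiplied
by 10 on read. Both the UCSC rmsk-style BED and raw `.out` layouts are
accepted because public repeat annotation circulates in both, and the two
dialects are held to byte-identical parsed records in the tests.

## First exons and TSSs

The first exon of a transcript is the 5'-most exon in transcription order:
minimal start on `+`, maximal end on `-`; the TSS is its first transcribed
base (`start` on `+`, `end - 1` on `-`). This is why unstranded exon
records are rejected at parse time — without strand there is no first
exon. Every transcript contributes exactly one first exon, so the
first-exon universe size always equals the transcript count.

Classification reports three flags: per-exon `te_derived`, per-transcript
`te_derived` (any exon), and per-transcript `te_first_exon`. Both
transcript-level statistics are surfaced separately because published
transcript-level percentages in this literature are sometimes
indistinguishable from first-exon percentages; keeping both avoids
guessing which one a table meant.

Reported percentages are rounded half-up to one decimal, and the raw ratio
is always carried alongside — rounding conventions in published reports
are not always internally consistent, so the exact ratio is the source of
truth.

## Matching assemblies with wiggle room

Two assemblies of the same RNA-seq data never agree on exact coordinates,
so records are matched with a tolerance: candidates lie on the same
chromosome and strand with `|Δstart| <= w` and `|Δend| <= w` (default
`w = 10` bp). From the candidates a one-to-one matching is chosen greedily
by ascending `|Δstart| + |Δend|`, with ties broken by coordinates and
record ids so the result is fully deterministic. One-to-one matching
prevents double counting in Venn-style shared/unique summaries. On small
random instances the tests verify the greedy result against exhaustive
enumeration of all maximum-cardinality assignments.

Transcript-level matching compares transcript *spans* (first-exon start to
last-exon end); exon-level matching compares exon intervals. Requiring
every internal splice boundary to match is a stricter notion of
equivalence that the pipeline deliberately does not impose — span matching
is the permissive reading, and the exon-level matcher is available when
boundary-resolved comparison is wanted.

## Family contribution, abundance and age

Each TE-derived exon contributes one hit to each *distinct* family among
its overlapping repeats. Hits are normalized by the family's genomic
background abundance; the default abundance unit is element count, with
summed bp as an option (both are defensible readings of "abundance", and
the ratio of the two differs by mean element length, which is why the
choice is explicit). Attribution defaults to the exon level — the
primitive from which transcript-level counts derive — with a
transcript-level switch.

Heterogeneity of contributions across families is tested with a chi-square
goodness-of-fit statistic against expectations proportional to abundance
(`sum((obs - exp)^2 / exp)`, `df = k - 1`); a uniform-expectation variant
is exposed because the proportional-vs-uniform choice is a modelling
decision, not a fact. The test suite drives 1000 multinomial null draws
through the statistic and requires the empirical type-I error at
`alpha = 0.05` to sit within three standard errors of 0.05.

Family age is proxied by mean millidiv (substitutions per kilobase since
divergence from the family consensus): rank 1 = youngest. Only the six
named families are ranked; `other` is tallied but unranked.

## Expression bins and the correlation test

TE-derived exons are sorted by FPKM (ties broken by coordinates for
reproducibility) and split into `nbins = 100` equal-*count* bins; with
`n = q * nbins + rem` exons, the first `rem` bins take `q + 1`. Equal
membership, not equal FPKM width, is the only binning under which a
heavy-tailed FPKM distribution yields comparable bins. Per bin, the mean
FPKM and the mean per-exon signal are computed; the default per-exon
signal is the *count* of overlapping peaks/clusters (summed bp and summed
score are options, and a `flank` parameter can symmetrically extend exons
before querying, default 0).

The trend is quantified by Pearson's r between the 100 bin means
(`n = 100`, matching the plotted trend), with significance from the
Student-t approximation

  t = r * sqrt(n - 2) / sqrt(1 - r^2),  df = n - 2,

two-sided. `pearson_t(0.6, 27)` is exactly `0.6 * 5 / 0.8 = 3.75`, which
the tests pin down along with the null identity `t(0) = 0` and
monotonicity in both r and n.

## Differential expression

Gene expression is the sum of the gene's transcripts' FPKM per sample.
Genes expressed in at least one group are tested with the classical
equal-variance two-sample t (`df = n_A + n_B - 2`; Welch available as an
option), after a `log2(x + 1)` transform that stabilizes variance at the
low replicate counts typical of these designs (`transform = "none"`
disables it). Multiplicity is handled by Benjamini–Hochberg q-values with
significance at `q < 0.05`, and the genes of interest are those both
significant and carrying a TE-derived first exon.

Degenerate inputs are defined rather than left to chance: zero pooled
variance with equal means gives `t = 0, p = 1`; zero pooled variance with
unequal means is an error (the statistic would be infinite).

A known limitation follows directly from the design being emulated: with
two replicates per group the pooled t has 2 degrees of freedom, whose
heavy tail bounds the smallest attainable p-value per gene. After BH
correction across thousands of genes, even strong planted shifts
(4-fold at ~10% replicate CV) are recovered at low rates. The test suite
therefore asserts what this test can honestly deliver — type-I error
control under the global null and power that increases monotonically with
effect size — not a high absolute recovery rate. Moderated-variance
methods (limma, DESeq2) exist precisely to escape this regime and would be
the practical choice for real two-replicate designs.

## The synthetic data generator

The generator produces the full input bundle with planted ground truth, so
every stage of the pipeline can be validated without downloads:

* **TE landscape** — six families, 600 elements each by default, uniform
  placement on a 2 x 5 Mb toy genome, family-specific length ranges, and
  millidiv drawn from per-family normals truncated at zero with means
  ordered Alu (110) < L1 (160) < LTR (200) < DNA (240) < L2 (280) <
  MIR (330) — the youngest-to-oldest order the age ranking should recover,
  with means separated far beyond the standard error of a 600-element
  family mean.
* **Transcriptome** — 2000 transcripts, `1 + min(Poisson(2), 5)` exons of
  100–300 bp separated by 200–2000 bp introns. A first exon is placed
  overlapping a uniformly chosen TE with probability `rho_first = 0.4`;
  later exons with `rho_later = 0.1`; non-planted exons are
  rejection-sampled to avoid every TE. Because avoidance is enforced, the
  classifier's flags must equal the planted labels *exactly*, which the
  tests check flag-for-flag — the planted rates are then recovered to
  binomial error by construction, not by luck.
* **Second assembly** — 70% of transcripts are duplicated with every exon
  boundary jittered by at most 10 bp (inside the matching tolerance), plus
  30% novel transcripts, giving the matcher a known shared fraction.
* **Expression** — lognormal per-gene baselines (meanlog 1, sdlog 1),
  replicate noise sdlog 0.1 (~10% CV), two replicates per condition, and a
  5% planted DE fraction shifted by 2 log2 units with random sign.
* **Signal tracks** — per exon and track, the expected peak count is
  `max(0, a + b log(FPKM + 1) + N(0, noise))` realized as rounded counts
  of 10-bp peaks placed inside the exon (`a = 0.2, b = 0.8, noise = 0.5`
  by default; `b = 0` yields a calibrated null track).

Identical config and seed give a byte-identical bundle, and ground truth
leaves the generator only through sidecar tables, never through the data
files.

What the generator does *not* emulate matters for interpreting green
tests: there is no sequence content (no splice-site motifs inside TEs), no
nested or fragmented repeats, transcripts of a gene are grouped by label
rather than sharing a locus, TE placement is uniform rather than
clustered in gene-rich regions, and signal tracks have no spatial
autocorrelation or antibody-specific peak geometry. Passing tests
demonstrate that the *computations* are correct and that planted structure
of the assumed form is recovered at the planted magnitude — they do not
certify biological conclusions about real ENCODE-scale data, whose
genome-wide counts also depend on aligner and assembler versions upstream
of this package.

## Problem sizes and runtime choices

The default desk scale — 2 chromosomes x 5 Mb, 3600 TEs, 2000 transcripts,
six tracks — runs the full pipeline in a few seconds; the repeated-seed
properties in the test suite (100 seeds of the 2000-transcript
classification, 100 positive/null signal seeds, 200 null DE replicates,
1000 multinomial draws) complete in about two minutes total. These sizes
were chosen as the smallest at which the binomial/3-SE bands in the tests
are meaningfully tight.

## Reproducing the numbers

`scripts/acceptance.R --seed N --out results/acceptance.json` re-runs the
worked-example fractions, the exact t identity, and the full synthetic
pipeline at the defaults above, writing every headline quantity as JSON.
The pipeline itself is exposed both as `run_pipeline()` and as the
`te-exonize` script (subcommands `simulate`, `classify`, `compare`,
`families`, `episignal`, `diffexp`, `run`) installed under
`inst/scripts/`.
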