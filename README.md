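# teexon — transposable-element exonization analysis

`teexon` quantifies the contribution of transposable elements (TEs) to the
coding sequences of assembled transcriptomes. Roughly half of the human
genome is TE-derived, and assembled transcripts — particularly those
missing from reference catalogs — frequently adopt TE sequence as exons
("exonization"). Given gene models (GTF + FPKM table), RepeatMasker repeat
annotation, and epigenetic peak/cluster calls (BED), the package answers,
with tested and deterministic code:

* which exons and transcripts are **TE-derived** (any genomic overlap with
  a repeat, half-open coordinates, ≥ 1 bp);
* whether **first exons and TSSs** are preferentially TE-derived relative
  to all exons;
* how many records two assemblies **share**, matching starts and ends
  with a bounded tolerance (±10 bp "wiggle") and greedy one-to-one
  pairing;
* which **TE families** contribute most after normalizing hit counts by
  genomic background abundance, with a χ² heterogeneity test
  (Σ (obs − exp)²/exp, df = k − 1) and a millidiv-based **age ranking**
  (rank 1 = youngest);
* whether TE-derived exon expression **correlates with epigenetic
  signal**: exons are sorted into 100 equal-count FPKM bins and the
  per-bin mean signal is tested with Pearson's r via the Student-t
  approximation *t = r√(n−2)/√(1−r²)*, df = n − 2;
* which genes are **differentially expressed** between two conditions
  (classical pooled two-sample t, BH-FDR q-values, q < 0.05) *and* carry
  a TE-derived first exon.

A synthetic-data generator with planted ground truth (TE landscape with
family-specific divergence, transcriptome with distinct first/later-exon
TE-overlap rates, two-condition expression with planted shifts, signal
tracks with a planted expression slope) makes the entire pipeline testable
offline; every statistical stage is validated against brute-force oracles
and recovery of the planted parameters.

It is aimed at genomicists studying repeat co-option and regulatory
genomics who want the co-location/enrichment arithmetic behind
exonization surveys as a reusable, audited library rather than one-off
scripts.

## Worked example

Everything below is generated — no downloads. The generator plants a 40%
TE-overlap rate on first exons and 10% on later exons:

```r
library(teexon)

cfg <- synthetic_config(seed = 42, n_transcripts = 500)
b   <- simulate_bundle(cfg, file.path(tempdir(), "demo"))

cls <- classify_exons(b$exons_a, b$tes)
rbind(fraction_te_derived(cls, "all_exons"),
      fraction_te_derived(cls, "first_exons"),
      fraction_te_derived(cls, "transcripts"))
#>         label numerator denominator  fraction percent
#> 1   all_exons       320        1480 0.2162162    21.6
#> 2 first_exons       203         500 0.4060000    40.6
#> 3 transcripts       262         500 0.5240000    52.4
```

The first-exon percent (40.6%) recovers the planted 0.4 to binomial error
and clearly exceeds the all-exon percent — the first-exon enrichment the
pipeline is built to detect. Per-family contributions, normalized by each
family's genomic abundance, with the age ranking from mean millidiv:

```r
fc <- family_contribution(cls)
fc$contribution
#>   family hits abundance normalized mean_millidiv age_rank
#> 1    Alu   65       600  0.1083333      112.2444        1
#> 2     L1   65       600  0.1083333      161.8986        2
#> 3    LTR   69       600  0.1150000      195.5121        3
#> 4    DNA   51       600  0.0850000      238.5269        4
#> 5     L2   69       600  0.1150000      277.4418        5
#> 6    MIR   65       600  0.1083333      329.3784        6
#> 7  other    0         0         NA            NA       NA
```

The age ranking recovers the planted youngest-to-oldest order Alu, L1,
LTR, DNA, L2, MIR. Binning the TE-derived exons by expression and
correlating the per-bin mean DHS peak count with the per-bin mean FPKM:

```r
fa <- b$fpkm[b$fpkm$sample %in% c("A1", "A2"), ]
tx_mean <- tapply(fa$fpkm, fa$transcript_id, mean)
te_ex <- cls$exons[cls$exons$te_derived, ]
te_ex$fpkm <- as.numeric(tx_mean[te_ex$transcript_id])

binned <- bin_by_expression(te_ex, nbins = 50)
dhs <- signal_per_exon(binned, b$signals$DHS, mode = "count")
correlate_profile(bin_profile(binned, list(DHS = dhs)))
#>   track         r  n        t df            p
#> 1   DHS 0.7994297 50 9.219347 48 3.381693e-12
```

The planted positive expression→signal slope comes back as a strong
positive trend (r ≈ 0.8, p ≈ 3e−12 from the t approximation; at the
defaults, `pearson_t(0.6, 27)` gives exactly t = 3.75). The whole chain —
classification, assembly comparison, families, signal correlation,
differential expression — can also be run in one call with
`run_pipeline(pipeline_config(...))`, or from a shell via the
`te-exonize` script (subcommands `simulate | classify | compare |
families | episignal | diffexp | run`) under `inst/scripts/`.

## Layout

* `R/` — IO (`read_gtf`, `read_repeatmasker`, `read_bed_features`),
  interval engine, classification, assembly matching, family
  contribution, expression-bin correlation, differential expression,
  synthetic generator, pipeline and CLI.
* `vignettes/te-exonization-methods.Rmd` — the model, parameter and
  design-decision write-up.
* `tests/testthat/` — unit, property and acceptance suites with
  brute-force oracles.
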