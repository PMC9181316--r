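---
title: "Benchmarking single-cell WGA kits with targeted STR panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking single-cell WGA kits with targeted STR panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strwga)
library(dplyr)
```

## The problem

Whole-genome amplification (WGA) is the first step of nearly every
single-cell genomic assay, and its distortions — locus and allele dropout,
uneven coverage, and polymerase slippage — dominate downstream noise.
Short tandem repeats (STRs) are unusually sensitive reporters of these
distortions: slippage during amplification adds or removes whole repeat
units, so the repeat-length histogram of a locus directly records the
amplification history. strwga evaluates WGA kits through a targeted STR
lens: a clonal diploid population with known genotypes is amplified under
parameterized kit profiles, targeted amplicon reads are counted into
per-locus repeat-number histograms, histograms are genotyped against a
simulated slippage model, and four kit-quality metrics are computed:

1. **Coverage** — loci sampled per cell, and the rate of failed cells
   (fewer than 500 sampled loci).
2. **Allelic balance** — the fitted proportion of the shorter allele at
   heterozygous loci (0.5 is ideal; 0/1 is allelic dropout).
3. **Consistency** — the number of loci jointly sampled by k-cell groups
   (k = 2..5) after downsampling every cell to 100,000 mapped reads.
4. **Amplification noise** — per-cell median of the fitted cycle count, in
   PCR-cycle equivalents, over AC-type loci.

A clonal population is the key device: population-wide, at most two
distinct alleles segregate per locus, so pooling all cells identifies the
heterozygous loci and their allele pair, against which each single cell
is then scored.

## The stutter model

Amplification is modelled as a per-cycle duplication/slippage process with
three parameters: duplication efficiency $e \in (0,1]$, per-duplication
slip probability $s \in [0,1)$, and down-bias $q \in [0,1]$ (a slip
removes one repeat unit with probability $q$, adds one otherwise).
Writing $f_c$ for the normalized repeat-length distribution after $c$
cycles, with $f_0$ a point mass at the allele:

$$
f_{c+1}(x) \;=\; \frac{\bigl(1 + e(1-s)\bigr)\,f_c(x)
  \;+\; e\,s\,\bigl(q\,f_c(x+1) + (1-q)\,f_c(x-1)\bigr)}{1+e}.
$$

This is the expected length distribution of the branching process in
which every molecule duplicates with probability $e$ per cycle and each
fresh copy slips with probability $s$; because slippage does not alter a
lineage's branching rate, the expected distribution equals the law of a
random final molecule, whose length performs a lazy random walk with
per-cycle slip probability $e\,s/(1+e)$. The test suite exploits exactly
this equivalence: an independent Monte-Carlo lineage simulation with
$10^5$ molecules must agree with the recursion to total-variation
distance below 0.01. Mass that would slip below one repeat unit is
clipped to one unit, so every distribution sums to 1 exactly.

Only single-unit slips are modelled; multi-unit slips exist but are a
minor mode and are out of scope. Defaults are $e = 0.95$, $s = 0.003$,
$q = 0.8$ (down-slips dominate in PCR). The fitted cycle count is always
expressed on this single idealized PCR-cycle scale, also for isothermal
MDA chemistries — "cycle-equivalent" noise makes kits with different
chemistries comparable on one axis.

## Genotyping by correlation against simulated stutter

A histogram is genotyped by searching one- and two-allele candidates
$w \cdot \mathrm{stutter}(a_1, c) + (1-w) \cdot \mathrm{stutter}(a_2, c)$
over a grid (cycles 0–90 in steps of 2; shorter-allele weight $w$ 0.05 to
0.95 in steps of 0.05; candidate alleles from the observed support ±2
units) and scoring each by Pearson correlation with the observed
histogram over the observed support padded by ±5 units. The best score
wins; a call requires correlation ≥ 0.95, otherwise the locus is a
`no_call` with the best candidate still reported. $w$ is by convention
the weight of the *shorter* allele (homozygous calls report $w = 1$),
which is why even an ideal bulk sample shows a slight positive bias:
longer repeats amplify marginally worse, and the reporting convention
aligns all such bias to the same side of 0.5.

Numerical details, all covered by tests:

* **Ties** (score difference below $10^{-9}$) resolve toward fewer
  alleles, then fewer cycles, then smaller allele separation, then the
  lower first allele — a pure spike is therefore called homozygous with
  zero cycles, not as any of its equally-correlated neighbours.
* **Degenerate windows**: if either vector is constant over the window,
  the score is 1 when both are point masses at the same repeat count and
  0 otherwise.
* **Information content**: the cycle number is informed only by the
  stutter mass (about 6% of reads at 40 cycles under default parameters),
  so per-locus cycle estimates at moderate depth carry a sampling error
  of several cycles. All noise analyses therefore aggregate per-cell
  medians over many loci, where the estimator is accurate and monotone;
  the test suite checks the median, not per-locus cycle values.
* **Adjacent alleles**: genotypes one repeat unit apart (e.g. 29/30)
  produce nearly indistinguishable one- and two-allele fits (score gap
  below 0.02 at default parameters). This is precisely why the
  population heterozygous filter requires a separation of at least three
  repeat units.

## STR-aware read counting

The defining construction for read assignment is alignment against a
length-permuted reference holding, for every locus, one record per
plausible repeat count (`left_flank + unit^r + right_flank`, default
range reference ±20). The implementation reproduces this with
flank-anchored counting: a read maps to a locus iff the last 15 bp of the
left flank and the first 15 bp of the right flank occur in order (≤1
mismatch each), the spanned interval is an exact multiple of the unit
length, and the interval matches `unit^r` with ≤1 mismatch. Reads are
tried forward then reverse-complemented; multi-locus candidates are
unmapped, as are tracts truncated by the read end (no partial counting).
The permuted-reference brute-force aligner is retained in the test suite
as the independent oracle, and the two must agree on ≥99% of
single-substitution reads. Anchor tolerances are assumptions exposed in
the function signatures, not measured properties of any particular
instrument.

## What the synthetic generator emulates — and what it does not

The generator stands in for a clonal human embryonic stem-cell
experiment: one diploid clone, about two dozen cells per kit across eight
kits (seven single-cell chemistries plus a bulk control), profiled on a
multi-thousand-locus STR panel by targeted capture. Its distortion model
per kit profile:

* global cell failure with probability `cell_failure_prob`, implemented
  as a Beta(1, 12) retention multiplier on both the surviving locus set
  and depth — degraded cells sample far fewer than 500 loci, reproducing
  the failed-cell mode rather than merely thinning reads;
* independent whole-locus dropout (`locus_dropout_prob`) and per-copy
  allele dropout (`allele_dropout_prob`);
* length bias: retained allele weights multiplied by
  $\exp(-\beta \cdot \text{repeat count})$ and renormalized, so longer
  alleles are under-amplified;
* per-locus amplification noise drawn from a truncated
  Normal(`noise_cycles_mean`, `noise_cycles_sd`), rounded, and fed to the
  stutter recursion;
* negative-binomial per-locus depth with mean
  `yield_mean / n_loci × capture`, where per-locus capture efficiencies
  are Beta(2, 2) — targeted enrichment is overdispersed, and small
  `yield_dispersion` values model the characteristic unevenness of MDA.

Reads are emitted either directly at the histogram level (the default:
read counts per locus per repeat length) or as literal single-end FASTQ
amplicon reads with substitution errors; the two paths are
read-for-read identical at zero sequencing error under the same seed,
which the tests verify against the truth sidecar. The pipeline default is
the histogram path; FASTQ emission exists for exercising the mapping
module and for interoperability.

Not emulated: probe hybridization chemistry and probe-arm design, index
hopping, paired-end overlap, sequence-composition-dependent slip rates,
indels in flanks, and copy-number or lineage structure. Consequently,
passing tests demonstrate that the *pipeline* recovers what the
*generator* encodes; they cannot certify kit rankings on real data, where
capture chemistry and slippage are richer than this model.

### Kit presets

The numeric values in `inst/extdata/kit_profiles.yaml` are synthetic.
Published kit comparisons support ordinal claims only — which kit yields
most, which balances best — not per-kit dropout probabilities. The
presets are therefore constrained to encode the established orderings
(RepliG-SC the highest yield and most sampled loci; Ampli1 the least
length bias and least locus dropout among PCR kits, hence the best
balance and k-cell consistency; PCR chemistries 10–20 cycle-equivalents
noisier than MDA; GenomePlex and TruePrime mostly failing; bulk
near-ideal), with magnitudes chosen once from feasibility arithmetic on
the negative-binomial zero probabilities before and after the
100,000-read downsampling. The end-to-end tests close the loop: the
pipeline's metrics must recover these configured orderings from raw
simulated reads.

## Threshold semantics

All analysis constants live in one `threshold_config()` object:

| constant | value | semantics |
|---|---|---|
| `min_het_depth` | 30 | pooled depth must be **strictly greater** |
| `min_allele_sep` | 3 | population alleles at least 3 units apart |
| `failed_cell_loci` | 500 | failed iff **strictly fewer** sampled loci |
| `consistency_reads` | 100,000 | exact without-replacement draw per cell |
| `min_cells_per_kit` | 5 | kits with fewer retained cells are excluded |
| `correlation_min` | 0.95 | minimum accepted fit correlation |
| `min_reads_per_locus_sampled` | 1 | a locus is "sampled" at ≥1 read |

Interpretation choices that the underlying constants leave open, decided
here and exposed in the configuration: the 30× clause applies to *pooled*
population coverage (the filter is defined on the global population, and
pooling is what makes the two-allele assumption usable); a locus counts
as sampled at a single mapped read; k-group consistency averages over all
$\binom{n}{k}$ groups when there are at most 10,000, else over 10,000
seeded random groups; the per-cell balance summary is the median absolute
deviation of $w$ from 0.5, while kit-level comparisons use the mean,
which is sensitive to the dropout mass at $w \in \{0, 1\}$; and the
per-cell noise statistic is a median over loci, chosen for robustness to
the heavy-tailed per-locus cycle estimates.

## Problem sizes and determinism

The default end-to-end scenario is 8 kits × 20 cells on a 2,000-locus
panel (~90% AC, 10% AGAT units, reference repeat counts 10–30), with
per-cell genotyping capped at the heterozygous set plus 300 additional
AC loci — medians over a few hundred loci per cell are stable, and the
cap keeps the grid search proportionate to what the metrics consume.
This scenario runs in minutes on one CPU. Every stochastic step draws
its seed from the master seed through a fixed counter scheme
(`kit index × 1000 + cell index`), so runs are bit-reproducible and
adding kits or cells never reshuffles earlier cells; rerunning any
downstream stage from the written `histograms.tsv` reproduces the
metric tables exactly.

## Known limitations

* Slip probability is length- and composition-independent; real STR
  slippage grows with repeat count, so cycle-equivalents are comparable
  across kits but not calibrated to any particular locus.
* The genotyper searches two alleles at most; contaminated or aneuploid
  inputs violate its assumptions.
* Flank mismatch tolerance is one substitution per anchor; indels in
  flanks make reads unmappable rather than shifted.
* Preset magnitudes are synthetic; only their orderings are meaningful,
  and only the orderings are asserted.
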