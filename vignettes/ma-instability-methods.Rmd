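---
title: "Methods: calling and quantifying genome instability in MA lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and quantifying genome instability in MA lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `malines`, in the spirit of a methods section: what each
stage assumes, where thresholds come from, and what the synthetic-data tests
do and do not establish about real sequencing data.

## The experimental design being modeled

A mutation-accumulation (MA) experiment passages a hybrid diploid yeast
strain through repeated single-colony bottlenecks: `s` independent isolates,
`n` passages, and an estimated 24 generations per passage. Sequencing the
end-point isolates against a wild-type control yields per-isolate variant
tables, genotypes at the dense heterozygous markers distinguishing the two
parental backgrounds, and window read-depth tracks. The assayed genome is
taken as 23 Mb over 16 chromosomes.

All coordinates inside the package are 0-based and half-open (BED
convention); 1-based VCF positions are converted at the I/O boundary.

## Event calling

**Background filtering.** Variants present in both an isolate and the
wild-type call set (keyed on chromosome, position, ref, alt) are
pre-existing background mutations and removed before any counting.

**SNVs.** Substitutions are collapsed onto the pyrimidine reference strand,
giving six types (C>T, C>A, C>G, T>C, T>A, T>G). InDels are ref/alt length
differences of at most 50 bp; larger losses must show in read depth and are
the province of the CR caller. The 50 bp cap is a convention separating
"small" InDels from large-fragment rearrangements; any event near the cap is
visible to both callers only through its depth footprint.

**LOH segmentation.** A segment is a maximal run of at least `min_run = 10`
homozygous markers, tolerating up to `max_gap = 1` heterozygous call between
consecutive homozygous markers (isolated genotyping miscalls). At the
default marker density of 1/400 bp, ten markers span roughly 4 kb — small
enough to catch gene-conversion tracts, large enough that a run of pure
miscalls (rate 0.002/marker) is vanishingly unlikely. A run touching the
first or last marker of a chromosome is terminal (T-LOH), else interstitial
(I-LOH). The segment span runs from the first to the last homozygous marker;
this tract span is also the "LOH window" used by the enrichment analysis
(the breakpoint-zone alternative — the transition region between flanking
het and hom markers — can be constructed from the reported marker indices,
but the tract is the default because it is the direct reading of a
homozygosity window).

**Copy-number segmentation.** Depth ratios are first recentered on the
euploid baseline (below), then smoothed per chromosome with a running median
(`smooth_k = 15` windows, ends kept unsmoothed). Windows strictly below
`del_max = 0.65` support deletion; strictly above `dup_min = 1.35`,
duplication — midpoints between the expected copy ratios 0.5/1.0/1.5 at
diploid baseline. Runs may bridge up to `cnv_max_gap = 5` non-qualifying
windows, must contain at least `min_windows = 4` qualifying windows and span
`min_span = 5` kb. Because a median filter transmits any plateau of at least
`(smooth_k + 1)/2` windows unchanged, the effective detection floor is 8
windows (8 kb at the default 1 kb tile); boundaries are refined outward on
the unsmoothed track so noise-free data are recovered exactly. Runs covering
at least `whole_chrom_frac = 90%` of a chromosome's windows — even when
noise splits them — are routed to the aneuploidy caller. A deletion is
terminal (T-Del) when it reaches within two windows of the effective
chromosome end (a trailing window shorter than half a tile is too noisy to
anchor this test and is ignored); values exactly on any threshold resolve
toward the no-call state.

**Euploid recentering.** Median normalization misbehaves in highly aneuploid
genomes: when several monosomic chromosomes and long terminal deletions put
a third of all windows at 0.5x, the genome median no longer sits on the
disomic coverage and every ratio is inflated by 10–15%. The caller therefore
relocates the euploid baseline as the modal window ratio (binned histogram,
refined by the median of ratios within ±0.15 of the mode) and rescales. This
assumes euploid windows are the plurality, which holds for any realistic
instability load; a track whose median is outside [0.5, 2] is rejected as
unnormalized.

**Aneuploidy.** Per chromosome, the mean ratio over windows outside called
CNV segments classifies: monosomy below 0.65, trisomy in (1.35, 1.75), 4–5
copies above 1.85. A chromosome at disomic depth whose whole-chromosome
homozygous-marker fraction reaches `upd_hom_min = 0.9` is a uniparental
diploid (UPD) — the operational separation of UPD from coincidental terminal
LOH, which rarely covers 90% of a chromosome's markers. Chromosomes with
fewer than three usable windows are flagged uncallable.

**Class exclusivity.** One physical event should appear once: LOH segments
overlapping a called deletion are absorbed into that CR (a hemizygous
deletion necessarily reads as homozygous markers), and LOH on chromosomes
called Mon or UPD is absorbed into the aneuploidy call. Whole-chromosome
depth runs never appear as CRs.

## Rates and cohort statistics

The per-bp per-division rate of a class with `N` events is
`N / (s * n * 24 * 23e6)`; the per-division rate omits the genome size.
Per-bp rates are reported for SNVs and InDels only — for segmental and
whole-chromosome events the per-division rate is the meaningful scale. Rates
carry exact Poisson 95% intervals on `N`. No multiple-testing correction is
applied across the five classes.

Group comparisons use the two-sided Wilcoxon rank-sum test: when the smaller
group has at most 8 observations the null distribution of the rank-sum
statistic is enumerated exhaustively over all group assignments (midranks
for ties, smaller tail doubled, capped at 1); larger groups use the normal
approximation with tie correction. Subtype compositions use Fisher's exact
test, exact up to a table total of 200 and seeded Monte Carlo beyond.

**Hypermutator detection.** MMR-loss-type hypermutators show a specific
dissociation: drastically elevated SNV+InDel counts with an unchanged
large-event load. An isolate is flagged when its point-mutation count
exceeds the cohort median by more than `k = 5` MADs, its C>T/G>A fraction
exceeds the cohort median fraction, and its LOH+CR+aneuploidy count stays
within `k` MADs of the cohort median. When a MAD degenerates to zero the
criterion falls back to a two-sided Poisson tail test at 1e-3 around the
median.

## LOH–element enrichment

With LOH windows from all isolates of a group unioned (so overlapping
windows are not double-counted), the expected number of elements inside the
windows under a uniform null is the covered length fraction times the total
element count. The observed count is the number of elements overlapping the
window union by at least 1 bp, each counted once. Significance is a
1-degree-of-freedom chi-square on the inside/outside split, without
continuity correction; results with expected < 1 are computed but flagged
unreliable, and a group without LOH yields untestable rows. Element tracks
are consumed as BED; the package builds three itself: centromere windows
(±2 kb around the midpoint — point features need width to overlap), G4
motifs (four runs of ≥3 G separated by loops of 1–7 bases, both strands,
overlaps merged — the standard quadruplex consensus), and GC classes
(500 bp windows; top/bottom decile by strict inequality, so a constant-GC
genome yields empty tracks; N bases leave the GC denominator and windows
over 50% N are dropped).

## APOBEC3B strand bias

A3B deaminates cytosines in transiently single-stranded DNA; the readout is
C>T on the top strand or G>A when the bottom strand was hit. Each signature
mutation between two adjacent replication origins gets a fractional position
`f = (pos - O_L) / (O_R - O_L)`. The template model assumes forks diverge
from each origin and terminate at the interval midpoint, with no origin
efficiency or firing-time weighting (an efficiency-weighted variant would
need origin activity data that the package does not bundle): left of the
midpoint the top strand is the lagging template, right of it the bottom
strand. Hence C>T marks lagging-strand ssDNA for `f < 0.5` and
leading-strand for `f > 0.5`; G>A is the mirror image; `f = 0.5` exactly is
ambiguous. Mutations outside the outermost origins are excluded because fork
direction there depends on unannotated flanking origins. The profile uses 10
half-open bins (last closed) — enough to resolve the crossing at `f = 0.5`
with modest counts — and the asymmetry statistic is the lagging fraction
with a two-sided exact binomial test against 0.5.

## The synthetic-data generator

The generator emulates the study conditions: a 16-chromosome, 23 Mb layout
with karyotype-proportional lengths and centromeres; Poisson marker maps at
1/400 bp (an emulation parameter — the true hybrid marker density is not a
published constant); per-division event rates defaulting to an RFA-depleted
cohort (SNV 4.28e-2, InDel 1.45e-2, LOH 3.13e-2, CR 1.41e-2, aneuploidy
1.2e-2 — the last chosen to sit at the same order as the CR rate, with
monosomy dominant); subtype weights with deletions at 65.7% of InDels,
terminal LOH at 65.8%, terminal deletions at 48.6% of CRs and monosomy at
83.7% of aneuploidies; 24 generations per passage (the rate-formula
constant, within the 20–25 range a 120 h passage implies). Depth is
negative-binomial per window (mean 50x, overdispersion 0.005, i.e. variance
= m + 0.005 m^2), allele fractions binomial given depth, marker genotypes
miscalled at 0.2%. Pre-existing background variants are shared between all
isolates and the wild type to exercise the filter. A3B mutations are placed
in inter-origin intervals and assigned to the lagging template of the
nearest-origin fork with probability `lagging_bias`. Aneuploidy is
whole-chromosome only; segmental dosage changes are CRs by construction.
Random streams are split per isolate, so isolate `k` is identical no matter
how many isolates follow it.

What the generator does **not** emulate: read-level artifacts (mappability,
GC-coverage bias, PCR duplicates), clustered or recurrent breakpoints,
segmental aneuploidy, marker-density heterogeneity along chromosomes, and
selection during passaging. Passing tests therefore demonstrate the
correctness of the calling and statistics on the stated noise model, not
robustness to alignment pathology.

## Test and verification scale

The checks run at deliberately desk-sized designs: noise-free recovery at
10 isolates x 3 passages (recall and precision must be exactly 1 per class
and subtype — every planted event, including its terminal/interstitial
label, is recovered); rate re-estimation at 30 x 5 against the exact Poisson
interval; 1,000-replicate uniform-null calibration of the enrichment
chi-square (mean ratio near 1, p < 0.05 fraction near 5%); a constructed
enrichment scenario with all elements inside windows covering 20% of the
genome (ratio 5 by construction); lagging-bias recovery at roughly 1,000 A3B
mutations; and hypermutator detection with 4 planted outliers (20x SNV rate,
C>T-skewed) among 31 isolates. Statistical backends are verified against
exhaustive enumeration (rank-sum for all group sizes up to 6, Fisher 2x2
against the hypergeometric closed form).

## Known limitations

* Terminal labels use the assayed track's ends, not telomere annotations; a
  subtelomeric interstitial event can be labeled terminal.
* The UPD rule misreads a chromosome whose markers are >90% homozygous from
  stacked independent LOH as UPD; the generator caps per-chromosome
  homozygosity below that, real data may not.
* CNV detection is thresholded segmentation, not a changepoint model; events
  shorter than ~8 windows are invisible by design, and depth ratios between
  0.65 and 1.35 (subclonal or mosaic dosage) are never called.
* The enrichment chi-square treats elements as independent; clustered
  elements inflate significance. A permutation alternative is a documented
  extension, not implemented.
* Fork geometry assumes midpoint termination and equal fork speeds;
  efficiency-weighted origin maps would shift `f` and could reclassify
  mutations near interval midpoints.
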