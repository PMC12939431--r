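# malines

Genome-instability analysis for mutation-accumulation (MA) experiments in
hybrid diploid yeast.

MA experiments propagate lineages through repeated single-colony bottlenecks
so that mutations accumulate with minimal selection; whole-genome sequencing
of the end-point isolates then gives nearly unbiased estimates of mutation
rates and spectra. In a hybrid diploid (two divergent parental backgrounds,
dense heterozygous markers), sequencing resolves five classes of genomic
variation: single-nucleotide variants (SNVs), small insertions/deletions
(InDels), loss of heterozygosity (LOH), chromosomal rearrangements (CRs),
and whole-chromosome aneuploidy. This regime is the workhorse for studying
replication-stress genotypes — e.g. strains with depleted Replication
Factor A (RPA), where terminal deletions, monosomy and LOH at replication
barriers dominate the landscape.

`malines` takes the tabular outputs of a standard short-read pipeline
(per-isolate variant tables, heterozygous-marker genotypes, normalized
window depth tracks) and provides:

* **event calling** — background-mutation filtering against a wild-type
  call set, six-type SNV classification, LOH segmentation with
  terminal/interstitial (T-LOH/I-LOH) labels, copy-number segmentation
  (T-Del/I-Del/Dup), and aneuploidy classing (Mon/UPD/Tri/Tet-Pen);
* **rate estimation** — the MA-design estimator
  `mu = N / (s x n x 24 x 23,000,000)` per bp per division (N = events,
  s = isolates, n = passages, 24 generations/passage, 23 Mb assayed
  genome), per-division rates for all five classes, Poisson CIs,
  fold-changes, Wilcoxon rank-sum and Fisher tests, and hypermutator
  (MMR-loss-type) lineage detection;
* **LOH-element enrichment** — expected counts from the genomic length
  fraction covered by LOH windows
  (`expected = loh_len / genome_len x n_elements`), observed counts by
  interval overlap, obs/exp ratios and a 1-df chi-square test, for element
  tracks such as centromeres, G-quadruplex (G4) motifs and GC-content
  classes (a G4 scanner and GC-window classifier are included);
* **APOBEC3B strand-bias analysis** — classification of C>T / G>A
  signature mutations, fractional positions between adjacent replication
  origins, leading/lagging template inference under diverging-fork
  geometry, binned profiles, and an exact binomial test of lagging-strand
  asymmetry;
* **a synthetic-data generator** — a 16-chromosome, 23 Mb hybrid-diploid
  emulation with Poisson marker maps, planted events of all five classes,
  negative-binomial depth noise, marker miscalls and A3B mutations with a
  configurable lagging-strand bias, so the whole pipeline is testable
  end-to-end without external data.

## Worked example

Simulate a small cohort (10 isolates, 3 passages of 24 generations), call
events, and estimate per-division rates:

```r
library(malines)

cfg    <- sim_config(seed = 42, isolates = 10, passages = 3)
sim    <- simulate_lineages(cfg)
events <- call_cohort_events(sim)
head(events[events$class != "SNV", ], 5)
#>  isolate class subtype chrom   start     end     support
#>   iso001 InDel     ins chr02 1289291 1289292   0.4464286
#>   iso001   LOH   T-LOH chr02     138  197935 478.0000000
#>   iso001   LOH   I-LOH chr02  573353  772378 474.0000000
#>   iso001   LOH   T-LOH chr14 1082355 1494203 996.0000000
#>   iso002 InDel     ins chr13 1475590 1475591   0.4444444

rate_table(events, s = 10, n = 3)
#>  group      class  N  s n per_division   per_bp   ci_lo  ci_hi
#>     MA        SNV 40 10 3      0.05556 2.42e-09 0.03969 0.0757
#>     MA      InDel  7 10 3      0.00972 4.23e-10 0.00391 0.0200
#>     MA        LOH 21 10 3      0.02917       NA 0.01805 0.0446
#>     MA         CR  9 10 3      0.01250       NA 0.00572 0.0237
#>     MA aneuploidy  7 10 3      0.00972       NA 0.00391 0.0200
```

Events are one row each: the T-LOH on `chr02` is a homozygosity tract
reaching the chromosome end supported by 478 consecutive homozygous
markers; `support` is the allele fraction for point variants and the mean
depth ratio for copy-number events. `per_division` is `N / (s*n*24)`;
`per_bp` divides by the 23 Mb assayed genome and is reported for point
mutations only.

The rate estimator on its own:

```r
mutation_rate(100, s = 31, n = 5, class_label = "SNV")
#> Rate (SNV): N = 100 over 3720 divisions
#>   per division: 0.02688  [95% CI 0.02187, 0.0327]
#>   per bp:       1.169e-09  [95% CI 9.51e-10, 1.422e-09]
```

`run_pipeline(list(seed = 5, out_dir = "demo"))` runs
simulate → call → rates → enrichment → strand bias in one step and writes
`events.tsv`, `rates.tsv`, `enrichment.tsv`, `strandbias.tsv` and a
`manifest.json` with output checksums; `make_report("demo")` summarizes a
finished run.

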