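# meiochip

Interval statistics and signal analysis for meiotic DSB hotspot ChIP maps,
driven by a fully seeded synthetic-data generator.

## The problem

In budding yeast, meiotic recombination starts with Spo11-catalysed DNA
double-strand breaks (DSBs) at hotspots. Two genome-wide readouts anchor the
analyses here:

* **RPA ChIP** — Rfa1-coated single-stranded DNA flanking resected DSB ends.
  Around each hotspot midpoint the signal forms two flanking enrichment
  bumps (the resection tracts), so a hotspot of intensity *I* contributes

  `λ(x) = I · [exp(−(x−m−δ)²/2s²) + exp(−(x−m+δ)²/2s²)]`

  on top of background, with flank offset `δ` and width `s`.
* **H3K56ac ChIP** — a histone-globular-domain acetylation enriched over
  transcribed gene bodies, depleted over hotspot cores and over the
  recombinationally cold rDNA, quantified as an occupancy-normalized double
  ratio `log2(IP/input) − log2(H3/input)`.

The package asks the questions such maps raise: where are the peaks; how do
peak sets colocalize (relative-distance statistics with interval-shuffling
nulls); what happens to a control RPA peak inventory in a mutant (here an
H3K56A-like mutant in which a configured subset of hotspots loses its signal
entirely, some are boosted, and the rest keep a fraction of their
amplitude); and how large are locus-level fold changes.

Because the real array data are not bundled, a first-class generator
(`sim_config()`, `build_genome()`, `simulate_tracks()`) plants all of this
structure — 4 chromosomes / 6 Mb, 50 bp bins, 1004 hotspots with log-normal
intensities, 661 suppressed and 182 boosted twofold in the mutant map,
multiplicative log-normal noise — and every downstream number can be checked
against the planted ground truth.

## Key statistics

* **Relative distance** (`relative_distance`): for a query midpoint between
  consecutive reference midpoints, `d = min(q−b_l, b_r−q)/(b_r−b_l)`;
  uniform on [0, 0.5] under independence, shifted toward 0 for clustering.
  `empirical_null()` shuffles the query set (`shuffle_intervals`, uniform
  non-overlapping placement avoiding forbidden regions) and reports add-one
  empirical p-values for both tails.
* **Peak calling** (`call_peaks`): transparent z-score thresholding with gap
  merging and a minimum width, summits at the maximum bin (leftmost on
  ties).
* **Differential classification** (`overlap_classify`,
  `classify_rpa_maps`): a control peak is *eliminated* if no mutant peak
  overlaps it; retained peaks split into *increased* vs *unaffected* by the
  mutant/control signal fold change at the peak (threshold `fc_up`).
* **Rank-sum test** (`ranksum_test`): Wilcoxon–Mann–Whitney U from
  midranks; exact null for n1+n2 ≤ 12 without ties, otherwise a
  tie-corrected, continuity-corrected normal approximation.
* **Profiles and quantification**: scaled-body metagene (`metagene`),
  anchor-point profiles (`anchor_profile`), locus enrichment against a
  negative-control region (`locus_enrichment`), control/mutant fold change
  (`fold_change_between`), track correlation (`track_pearson`),
  peak-associated vs random gene expression (`expression_association`).

Standard formats are supported at the boundary: BED3–BED6, bedGraph on a
fixed bin grid, GFF3 genes, chromosome-sizes TSV. Coordinates are 0-based
half-open throughout.

## Worked example

```r
library(meiochip)

sim <- simulate_fixture(sim_config(seed = 42))   # ~4 s, in memory
res <- classify_rpa_maps(sim$tracks)
res$classification
#> OverlapClassification: 1004 control peaks
#>   eliminated 661 (65.8%), unaffected 161, increased 182 (fc_up=1.5)

fold_change_between(sim$tracks$RPA_ctrl, sim$tracks$RPA_mut,
                    sim$truth$named_loci$BUD23like)
#> FoldChangeEstimate (ctrl/mut): 2.734 (means 152.8 / 55.87)
```

The classification recovers the planted truth exactly: of 1004 control RPA
peaks, the 661 whose mutant signal was suppressed are eliminated (65.8%),
343 are retained, and the 182 boosted hotspots are called increased at a
1.5-fold threshold. The fold change at the registered `BUD23like` hotspot
(~2.7 here; expectation 3 under the planted one-third mutant efficiency)
quantifies the mutant's signal loss at an unsuppressed hotspot.

H3K56ac peaks avoid DSB hotspots while peak-associated genes are more
highly expressed:

```r
k56 <- double_ratio(sim$tracks$H3K56ac, sim$tracks$input, sim$tracks$H3)
k56_peaks <- call_peaks(k56, z_threshold = 1.2)
hs <- sim$truth$hotspots
hs_fs <- feature_set(sim$truth$genome,
                     data.frame(chrom = hs$chrom, start = hs$mid, end = hs$mid + 1))
en <- empirical_null(k56_peaks, hs_fs, "mean_reldist", n_perm = 99, seed = 52,
                     forbidden = sim$truth$cold_region)
#> mean reldist 0.275 (shuffle null 0.250), repulsion p = 0.01

expression_association(sim$expression, sim$truth$genes, k56_peaks,
                       seed = 54)$test_greater
#> RankSumResult (normal, greater): U=489851.0 z=5.490 p=2.015e-08 (n1=924, n2=924)
```

`run_pipeline(pipeline_config(seed = 42), out_dir = "run")` chains all of
the above (simulate → normalize → call peaks → reldist nulls → profiles →
classification → quantification → expression test) into `results.json`,
and `make_report("run")` renders a markdown summary.

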