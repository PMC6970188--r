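---
title: "Models and methods behind meiochip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meiochip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

meiochip analyses binned ChIP signal over meiotic DSB hotspots: it
normalizes tracks, calls peaks, measures colocalization between interval
sets against randomized nulls, profiles signal over genes and anchor
points, and classifies a control peak inventory against a mutant map. All
analyses run on synthetic data with planted ground truth, so every
statistic the package reports can be checked against what was planted.
This vignette explains the generative model, the statistical procedures,
the tunable parameters, and the design decisions taken where the analysis
design was genuinely open.

## The generative model

The generator builds a yeast-like coordinate universe and five signal
tracks on a common bin grid. Defaults: 4 chromosomes totalling 6 Mb,
`bin_width = 50` bp (~120,000 bins). Every per-bin observation is

  observed = lambda * exp(eps),  eps ~ N(0, noise_sigma^2),

independent across bins and tracks, with `noise_sigma = 0.25` by default.
Multiplicative log-normal noise was chosen because ratio-type ChIP signal
is positive and right-skewed; note `E[exp(eps)] = exp(sigma^2/2)` (about
1.032 at the default), an inflation the test suite verifies empirically.
With `noise_sigma = 0` every track equals its expectation `lambda` exactly,
which is what makes closed-form oracle tests possible
(`track_lambdas()` exposes the expectation, and the test suite recomputes
it with an independent implementation).

The per-track expectations:

* **input** — flat background (`background = 1`, the unit of signal; all
  downstream ratios are scale-invariant, which the tests assert).
* **H3 occupancy** — background with dips (`ndr_factor = 0.4`) at promoter
  nucleosome-depleted regions (`ndr_width = 300` bp upstream of each gene
  start, strand-aware) and at hotspot cores.
* **H3K56ac** — a plateau `background * k56_factor(gene)` over each gene
  body, where `k56_factor` is log-normal around `k56_orf_enrichment = 3`
  with spread `k56_gene_sdlog = 0.5`; multiplied by `k56_depletion = 0.3`
  within `core_half_width = 500` bp of a hotspot midpoint; forced to
  background inside the cold region.
* **RPA (control)** — background plus, per hotspot, two Gaussian resection
  flanks at `mid ± flank_offset` (800 bp) with sd `flank_sd` (400 bp) and
  peak amplitude equal to the hotspot intensity. The two-bump geometry
  encodes that RPA coats resected single-stranded DNA *flanking* the break,
  not the break point itself. Bumps are evaluated within
  `flank_offset + 5 * flank_sd` of the midpoint; the truncation is part of
  the model definition.
* **RPA (mutant)** — as control, but a configured subset of hotspots
  (`n_suppressed = 661` of `n_hotspots = 1004`) contributes nothing,
  `n_boosted = 182` of the remainder contribute `boost_factor = 2` times
  their amplitude, and all others contribute `mut_efficiency = 1/3` of it.
  These defaults make the differential-classification arithmetic a
  recoverable planted truth (661 eliminated = 65.8%, 343 retained, 182
  increased), and the one-third efficiency yields a threefold control/mutant
  fold change at any unchanged hotspot.

Hotspot intensities are log-normal (`meanlog = log(300)`, `sdlog = 0.4`).
The amplitude scale relative to background is a free choice — microarray
dynamic range is arbitrary — and was set once for detectability: the
weakest mutant-attenuated hotspot still clears the peak-calling threshold
by a wide margin, and background noise never does. Genome layout: genes
(2000, lengths 500–3000 bp, grid-aligned, non-overlapping with at least
400 bp intergenic gaps) are placed by an exact uniform non-overlapping
construction; hotspot midpoints occupy quasi-regular slots that guarantee
`min_hotspot_spacing = 5000` bp so that the resection flanks of neighbours
never fuse into one called peak (without this floor the planted peak count
is unrecoverable at this hotspot density), snapping to a promoter inside
the slot with probability 0.8; one contiguous cold rDNA-like region
(150 kb, centred on the last chromosome) carries no genes or hotspots and
has background H3K56ac. Three loci are registered in the ground truth: two
median-intensity hotspots left unchanged in the mutant (`BUD23like`,
`ERG1like`) and a `rDNAlike` window inside the cold region, used as the
negative control for locus enrichment.

Expression: the top quartile of genes by planted H3K56ac factor forms the
"high" tier; mRNA levels are log-normal with the high tier's location
shifted by `expr_shift_log2 = 1` log2 unit. With seeds fixed, every output
(annotation files, tracks, expression table) is byte-reproducible; the
generator seed also derives the noise stream (`seed + 1`) and expression
stream (`seed + 2`), and `simulate_tracks(truth, noise_seed =)` draws
independent replicates of one landscape — used for replicate correlation
and for fold-change replicate statistics.

What the generator does **not** emulate: read-level sampling (no
FASTQ/BAM), probe-level microarray behaviour, nucleosome-scale structure,
replication timing, spatially correlated noise, mappability artefacts, or
copy-number effects. Passing tests therefore demonstrate correctness of
the statistical machinery on data with the assumed structure, not
robustness to every artefact of real arrays.

## Normalization

`log2_ratio(ip, control, pseudocount)` and
`double_ratio(ip, input, occupancy, pseudocount)` implement the standard
enrichment ratios; the double ratio is the occupancy-normalized form
`log2((ip+pc)/(input+pc)) − log2((occ+pc)/(input+pc))` used for the
histone-mark track. A ratio-of-ratios was chosen over a regression
correction as the simplest reading of "normalized to H3 occupancy"; the
pseudocount default is 1.0 on linear tracks and is config-exposed. Masked
bins (NA) propagate through every operation and are excluded from all
statistics. `zscore_track` uses the population (divisor-n) standard
deviation — bin counts are in the 10^4–10^5 range, and fixing the
convention keeps test values exact.

## Peak calling

`call_peaks` is a deliberately transparent threshold caller: z-score the
track, take bins at or above `z_threshold`, merge candidate runs separated
by at most `merge_gap_bins` (2), drop runs shorter than `min_width_bins`
(3), annotate each peak with its summit (maximum bin midpoint, leftmost on
ties — a determinism rule) and mean raw signal. Model-based callers were
an explicit non-goal; with a threshold caller every downstream count is
auditable against the planted truth. Degenerate input: a zero-variance
track returns zero peaks (a flat track has no peaks) rather than failing
in the z-scoring step. The optional `baseline` argument fixes the
z-scoring moments, which makes calling idempotent when a track is
restricted to previously called regions.

In the pipeline, RPA peaks are called on the **log2(RPA/input)** track
rather than the raw linear track. The raw track's genome-wide moments are
dominated by heavy-tailed hotspot intensities, so a z-threshold on the
linear scale maps to an unstable raw cutoff; the log scale bounds the
dynamic range and the implied cutoff is stable across seeds and genome
sizes. The thresholds were calibrated once against the default fixture and
frozen in `pipeline_config()`: `z_rpa_ctrl = −0.88` and `z_rpa_mut = 0`
(negative/zero z values are expected here — resection flanks cover more
than half of the genome, so the genome-wide mean lies far above the
inter-hotspot background), and `z_k56 = 1.2` for the normalized H3K56ac
track (selecting high-acetylation gene bodies). The H3K56ac and mutant-RPA
baselines differ from the control's, hence per-track thresholds.

## Interval statistics

**Relative distance.** For query midpoint `q` between flanking reference
midpoints, `d = min(q−b_l, b_r−q)/(b_r−b_l)` lies in [0, 0.5] and is
uniform when the sets are independent; values crowding 0 indicate
clustering, values crowding 0.5 repulsion. Queries outside the span of
reference points on their chromosome are skipped and counted, not clamped
— clamping would bias the tails. The analytic independence reference
(mean 0.25) and a shuffle null are both available.

**Shuffling.** `shuffle_intervals` preserves the count and per-chromosome
length multiset (mode `within_chromosome`, the default, mirrors a
randomized chromosomal distribution while preserving chromosome
composition) and places intervals uniformly among non-overlapping
configurations by the stars-and-bars construction, avoiding forbidden
regions (the cold region, in the pipeline); segment assignment is retried
up to 1000 rounds before an insufficient-space error.

**Empirical p-values.** `empirical_null` uses the add-one convention
`p = (1 + #{null ≤ obs})/(n_perm + 1)`, which never reports zero and is
valid (stochastically no smaller than uniform) under the null; both tails
are always reported. The calibration test draws 200 replicate
query/reference pairs at `n_perm = 99` and checks uniformity of the
p-values.

**Differential classification.** A control peak is *eliminated* exactly
when no mutant peak overlaps it by at least 1 bp — a Venn-membership
reading of peak loss; the signal fold change (mutant/control mean over the
control peak midpoint ± `flank_bp = 2000` bp, on the raw linear tracks)
only splits retained peaks into *increased* (`fc ≥ fc_up`, default 1.5)
versus *unaffected*. Retained peaks with zero or fully masked control
signal are excluded from the fold-change split, counted as unaffected, and
reported. The three labels always partition the control set, asserted on
every run.

**Rank-sum test.** `ranksum_test` computes U from midranks and uses the
exact permutation null when `n1 + n2 ≤ 12` with no ties (verified against
a full-enumeration oracle over all assignments of small value grids, and
against `stats::wilcox.test`), otherwise a normal approximation with
tie-corrected variance and a 0.5 continuity correction (verified against a
Monte-Carlo permutation estimate). Degenerate complete-tie input returns
p = 1.

## Profiles and quantification

`metagene` rescales each gene body to `body_bins = 50` segments by
overlap-weighted means, adds fixed-width flanks (500 bp in 10 segments per
side), reverses minus-strand genes so the axis reads 5'→3', and summarizes
per segment with the median by default (ChIP signal across genes is
skewed; the median is the conventional robust choice). Genes shorter than
`body_bins` track bins are skipped and counted. `anchor_profile` divides
`± window_bp` (2 kb) around each anchor midpoint into `n_bins = 80`
segments; windows truncated at chromosome ends contribute NA and the
per-segment n is adjusted. Anchor profiles report unscaled summaries; a
center/flank ratio read off the profile recovers the planted H3K56ac
depletion factor exactly at zero noise when anchors are restricted to
intragenic hotspots (so that the gene plateau cancels).

`locus_enrichment` is the ratio of mean signal in a target region to a
negative-control region — a qPCR-style enrichment computed from tracks
rather than Ct values, with the orientation always recorded.
`fold_change_between` reports mean control / mean mutant over one region
(orientation ctrl/mut, so a threefold mutant loss reads as 3).
`expression_association` contrasts genes overlapped by peaks against an
equally sized random gene sample (not against all remaining genes — the
comparison population deliberately includes high-tier genes), reporting
one- and two-sided rank-sum p-values.

## Pipeline, determinism, degenerate inputs

`run_pipeline` chains simulate → normalize → call peaks → reldist nulls →
profiles → classification → quantification → replicate correlation →
expression association, writing `results.json`, peak BEDs, the per-peak
classification table and a log; `make_report` renders the headline
numbers. Every random stream has an explicit seed key, and a rerun with
the same configuration is byte-identical. When the configuration plants no
hotspots, the RPA maps contain background only; thresholding a signal-free
track against its own baseline is undefined, so the pipeline reports empty
RPA peak sets and an empty classification with an explicit
`rpa_background_only` flag. The package's functions, this pipeline and
`scripts/acceptance.R` are the interface; there is no separate shell
binary.

## Problem sizes used by the test suite

The full study-scale fixture (6 Mb, 1004 hotspots) is used where its
arithmetic is the point: the differential classification, the locus fold
change and the expression association. Structural and calibration
properties (generator closed form, determinism, pipeline behaviour,
replicate fold-change statistics) run on scaled-down fixtures — 0.7 Mb
with 112 hotspots at the same hotspot density and signal-to-background, or
0.2 Mb with 30 hotspots for 100-replicate noise studies — chosen so the
whole suite completes in a few minutes while exercising identical code
paths and calibrated thresholds.

## Known limitations

* The peak caller is a global threshold method; it has no local background
  model and would mis-handle strong chromosome-scale covariates (which the
  generator does not produce).
* The shuffle null preserves lengths and chromosome assignment but not any
  further genomic covariate structure (no GC or annotation-matched
  workspaces).
* Relative-distance statistics need at least two reference points per
  chromosome; sparse reference classes lose the queries on their empty
  chromosomes (reported via `n_skipped`).
* The z-threshold calibration is tied to the generator's
  signal-to-background regime; applying `pipeline_config()` thresholds to
  tracks with a very different dynamic range requires recalibration
  (`track_baseline` exposes the moments needed).
* Expression is modelled as a two-tier log-normal; there is no
  length/GC/count structure, so the expression association tests the
  statistic, not an RNA-seq workflow.
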