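---
title: "Developmental trajectories of promoter histone methylation: models and methods"
author: "epitraject"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developmental trajectories of promoter histone methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitraject)
```

## The scientific problem

H3K4me3 — trimethylation of histone H3 lysine 4 — marks active
transcription start sites. In sorted neuronal (NeuN+) nuclei from human
prefrontal cortex, the genome-wide H3K4me3 landscape is remodeled during
development: a minority of promoter-proximal loci gain or lose the mark
along a unidirectional, saturating trajectory, with the steepest changes
between the late prenatal period and the first one or two years of life and
progressively slower changes thereafter. `epitraject` implements the full
quantitative pipeline for detecting and characterising such trajectories in
an age-structured ChIP-seq cohort — quantification, peak calling, cohort
structure, trajectory classification, clustering, and integration with CpG
methylation and expression — together with a seeded synthetic-cohort
generator so that every stage can be validated against planted ground
truth.

## Coordinates, intervals and promoters

All coordinates are 0-based half-open (`[start, end)`), the BED convention;
1-based formats must be converted at the reader boundary. Interval merging
(`merge_intervals()`) treats abutting intervals (`[a,b)` + `[b,c)`) as one
region by default: the merged set is used only for counting, where the
distinction is irrelevant, and merging keeps the promoter set disjoint.
A `merge_abutting = FALSE` flag restores overlap-only merging.

Promoters are TSS ± 2 kb (`build_promoters()`, flank configurable), merged
when they overlap, with the gene map carried through the merge. chrY is
excluded at annotation load by default, matching the promoter-vector and
clustering analyses; a flag retains it. Strand is carried but ignored by
all counting, as ChIP-seq reads are effectively unstranded after mapping.

## Density scale

Counts use at-least-one-base overlap of the mapped read interval (36 bp by
default, no fragment extension). The density unit is fixed as

> reads per bp per million promoter-anchored reads:
> `density = count / (length * promoter_total / 1e6)`

where `promoter_total` is the sample's reads overlapping any merged
promoter region — a library-size surrogate robust to genome-wide background
differences. On this scale the default thresholds (trajectory floor 0.01,
differential floor 0.005) are meaningful; both remain configurable since
density units are convention, not physics. The heatmap-style correlation
analysis composes region-length normalization with the promoter-anchored
denominator; the two normalizations commute and their composition is what
`build_density_matrix()` emits.

## Peak calling

`call_peaks()` is a deliberately simple local-Poisson caller: fixed windows
of width `2*bw` (bw = 230 bp) advanced by `bw`, a window's background
expectation taken as the **maximum** of depth-scaled control rates at 1 kb,
5 kb, 10 kb and genome-wide scales (the max-of-scales rule protects against
locally elevated background), and a Poisson upper-tail threshold of 1e-5.
Control scaling uses the ratio of total mapped reads, not promoter reads:
background scaling should not depend on signal-rich regions. There is no
model shifting, duplicate filtering or fragment-size estimation; p-values
are kept as log10 to avoid underflow.

Significant windows merge into peaks. Each peak is then **re-scored over
its full extent** — the aggregated treatment count against the peak-scale
local lambda — and this aggregated p is the peak's primary p-value, with
the minimum member-window p kept alongside (`log10p_window`). Aggregation
is the package's own choice: windows of 460 bp cap the evidence any single
window can carry, so window-level minima cannot reach the extreme-tail
regime (1e-20) in which the differential filters operate, whereas the
aggregated count over a multi-kilobase peak can — this mirrors how
full-scale callers report peak significance. Consequently, absolute peak
counts from the original full-scale caller are not comparable and are not
targets.

Differential calls (`differential_peak_count()`) treat one sample as
treatment and the other as control and additionally require p < 1e-20,
promoter-normalized density ratio > 4 and density > 0.005 in the enriched
sample. The p threshold is numerically tied to this caller and is exposed
in configuration. The ratio uses peak-local promoter-normalized densities;
a zero denominator counts as an infinite ratio.

## Trajectory classification

Samples are grouped as prenatal (age ≤ 0 years on the continuous axis,
i.e. at or before a 40-gestational-week term), infant (0–1 yr) and older
(≥ 1 yr). Gestational ages convert as `(gw - 40) * 7 / 365.25`. A
40-gw specimen is collected before delivery and is grouped prenatal; this
keeps the three-prenatal / three-infant / 25-older design intact.

A region is called **down** iff (1) prenatal mean density ≥ 0.01, (2)
prenatal/older fold ≥ 2, (3) two-sided t-test p ≤ 0.05 comparing the three
prenatal with the 25 older samples, and (4) length ≥ 1 kb. **Up** is the
reciprocal: the floor applies to the older group and the fold inverts —
reading "reciprocal criteria" literally. Infants never enter the test but
appear in all profiles. The t-test is Welch (unequal variance) by default
because a 3-vs-25 comparison has no business assuming equal variances; a
pooled-variance flag is provided since the original description says only
"t-test". Regions with zero variance in both groups get an undefined p and
class `none`.

For clustering, regions ≥ 1 kb with a group mean above the floor in either
tested group (chrY excluded) are max-normalized — each profile divided by
its maximum, giving values in [0, 1] with maximum exactly 1 — and
partitioned by Euclidean k-means with k = 5, ten random restarts under a
fixed seed (base R `kmeans`, the same procedure the original analysis
used). Cluster trends are labeled by the Spearman rank correlation of the
centroid with age (|rho| ≥ 0.5 ⇒ up/down, else flat); the threshold is this
package's formalisation of labels that were originally assigned by
inspection.

## Cohort structure

Every ordered sample pair yields a differential-peak count; the resulting
asymmetric matrix (rows = samples as feature vectors) is mean-centred by
column — without unit-variance scaling, since all entries share the count
scale and scaling would inflate near-empty columns — and decomposed by
eigendecomposition of the column covariance. The matrix is used as-is
(the most literal reading of using the pairwise matrix as PCA input); a
`symmetrize` flag adds the transpose first. Components are ordered by
descending eigenvalue with signs fixed so the first loading is
non-negative, making scores bit-reproducible. Separation of prenatal
samples on PC1 (and prenatal+infant on PC2) is quantified by a rank-sum
test taken one-sided in the direction of the observed difference, because
the component sign carries no meaning; tied scores fall back to the normal
approximation. The observed variance fractions depend on cohort and caller
and are reported, not targeted.

## Integration

Peaks link to genes when a TSS lies within 2 kb (inclusive) of the peak.
Genes with two called promoter peaks whose TSSs are ≤ 100 kb apart are
classified `up+down`, `up+up` or `down+down`. Per-CpG methylation change
is a Welch t-test (prenatal vs older) with Benjamini–Hochberg FDR across
tested CpGs (constant CpGs are excluded from the family); direction is the
sign of the older-minus-prenatal mean at the chosen cutoff (0.05 default,
1e-10 as the robustness alternative). The histone/methylation
anti-correlation is a 2×2 contingency — CpGs near up- vs down-trajectory
genes against significant methylation decrease — tested by the
hypergeometric upper tail on the up row. The worked reconstruction from
the printed marginal percentages (62 of 394 vs 46 of 744) gives
p ≈ 3.0e-7; the exact construction behind the originally printed 7.0e-8
(CpG- vs gene-level, sidedness, universe) is not recoverable from the
text, and the reconstruction agrees to within one order of magnitude.
Over-representation uses the same hypergeometric tail per term over a flat
term–gene table (no ontology graph), BH-adjusted, with enrichment score
`-log10(FDR)` and a 0.85 inclusion FDR for comparing enrichment landscapes
between gene sets.

## The synthetic cohort

The generator's defaults are the package's reference study conditions:

* **Design**: the 31 ChIP + 1 input cohort at the published ages (34 gw to
  81 yr; three prenatal, three infant), or a reduced 12-sample cohort with
  three samples per age band (gestational, 0–1, 3–14, 15–25 yr) for the
  quadratic all-pairs analysis.
* **Regions**: 2000 candidate regions (500 in the reduced design) of
  1.2–1.8 kb on a 10 kb grid across two toy chromosomes; 66% carry their
  gene's TSS inside the region (mirroring the roughly two-thirds
  TSS-proximal share of regulated loci), the rest sit 5 kb from a TSS; 5%
  of regions participate in two-promoter genes ≤ 100 kb apart.
* **Kinetics**: each region follows
  `d(age) = d_inf + (d_start - d_inf) * exp(-(age - a0)/tau)` — the
  monotone-saturating form implied by unidirectional exponential change.
  10% of regions are planted down, 5% up, the rest flat. Directional
  regions span a 5-fold dynamic range with the high end at density
  0.4–0.6 and flat regions at 0.1–0.3; time constants tau are uniform on
  0.5–2 yr, chosen so the largest shifts occur within the first one or
  two years of life. No quantitative half-lives were ever published; tau
  is a free parameter of the emulation.
* **Reads**: expected enriched reads are `density × length ×
  prom_depth/1e6` with a nominal promoter depth of 2e5 (so a density-0.5,
  1.5 kb region carries ~150 reads — enough for genuinely differential
  regions to reach the 1e-20 p regime), placed uniformly within the region
  extended by half a fragment (115 bp) per side; background is uniform at
  0.005 reads/bp. Input samples receive background only. A master seed
  spawns per-sample and per-table substreams, so outputs are byte-stable
  and order-independent.
* **Methylation / expression**: a fraction `anti_rho` of directional genes
  gets CpG beta values moving opposite to the histone trajectory along the
  same time constant (beta 0.3–0.7, truncated-Gaussian noise sd 0.05);
  expression is an affine image of the density trajectory plus Gaussian
  noise on the log2 scale.

What the generator does **not** emulate: sequence content and mappability,
fragment-length distributions, duplicate reads, GC bias, copy-number or
allelic effects, non-monotone ("up-down") trajectories, and biological
replicate-to-replicate variance beyond Poisson sampling. Because the
realized promoter denominator is itself a function of the planted signal,
the realized density scale sits a small constant factor above the planted
scale, and flat-region profiles acquire a weak compositional age trend of
a few percent — a faithful analogue of normalization composition effects
in real data (visible in tests as flat regions joining weakly-trending
clusters; the fold-change gate keeps them out of the up/down calls).
Passing recovery tests on these cohorts therefore demonstrates the
correctness of the decision rules and their power under Poisson noise at
the planted effect sizes, not robustness to every artefact of real
chromatin data.

## Numerical choices and degenerate inputs

* Poisson and hypergeometric tails are computed through the log-space
  distribution functions (`ppois`, `phyper`); `P(X >= 0) = 1` by
  convention. Tests cross-check both against direct summation and
  exhaustive enumeration.
* Zero-variance samples in the correlation matrix become NA rows/columns
  and are reported; zero promoter reads exclude a sample with a warning;
  an all-zero differential matrix is a refused PCA ("no structure").
* k-means determinism comes from a fixed seed plus ten restarts; the best
  restart by within-cluster sum of squares wins.
* Chromosomes present in treatment but absent from control fall back to
  the genome-wide control rate, with a message.

## Problem sizes

The bundled validation runs use the 31-sample / 2000-region reference
cohort for recovery and clustering (20 seeds), the 12-sample / 500-region
reduced cohort for the all-pairs structure analysis (20 seeds), 1 Mb
background-only simulations for the null control (20 seeds), and a
400-region cohort for the methylation contingency sweep (20 seeds per
anti-correlation level) — sizes chosen so the complete validation executes
in minutes on a single core while keeping every test well-powered.

## Worked example

```{r example, eval = FALSE}
co <- simulate_cohort(cohort_config(seed = 1))
prom <- build_promoters(co$annotation)
chip <- co$meta$sample_id[co$meta$fraction == "chip"]
dm <- build_density_matrix(co$reads[chip], co$regions, prom)
groups <- assign_age_groups(co$meta$age_years[match(chip, co$meta$sample_id)])
calls <- classify_up_down(dm, groups)
print(calls)
table(planted = co$models$klass, called = calls$klass)
```

## Known limitations

The peak caller is a documented simplification, not a reimplementation of
any published caller; absolute peak counts, peak boundaries and extreme
p-values are caller-specific. The differential p threshold (1e-20)
therefore selects a different operating point than it did in the original
analysis. The synthetic cohort provides Poisson read noise only, so
recovery rates here are upper bounds on what identical thresholds achieve
on biological replicates. The enrichment module performs flat-table
over-representation without ontology structure.
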