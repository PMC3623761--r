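# epitraject

Developmental trajectory analysis of promoter histone methylation
(H3K4me3) in age-structured ChIP-seq cohorts — written for epigenomics
researchers who want a transparent, fully testable implementation of the
classic neuronal-chromatin developmental pipeline.

H3K4me3 marks active transcription start sites. Across a cohort spanning
the late prenatal period to old age, a minority of promoter-proximal loci
gain or lose the mark along a monotone, saturating trajectory

    d(age) = d_inf + (d_start − d_inf) · exp(−(age − a0)/τ)

with the steepest changes around birth and the first years of life. The
package detects these loci and characterises the cohort:

* **Quantification** — reads counted in merged TSS ± 2 kb promoter regions,
  densities in reads/bp per million promoter-anchored reads, pairwise
  Pearson correlation of samples.
* **Peak calling** — a simplified sliding-window local-Poisson caller
  (bw = 230, tsize = 36, p ≤ 1e-5, max of 1 kb/5 kb/10 kb/genome-wide
  background scales).
* **Cohort structure** — differential-peak counts for every ordered sample
  pair (p < 1e-20, ratio > 4, density > 0.005), PCA of the resulting
  matrix, rank-sum separation of the prenatal group on PC1.
* **Trajectory classification** — *down* peaks: prenatal mean ≥ 0.01,
  prenatal/older fold ≥ 2, Welch t-test p ≤ 0.05 (3 prenatal vs 25 older
  samples), length ≥ 1 kb; *up* peaks by the reciprocal criteria. Plus
  k-means (k = 5) on max-normalized age profiles with Spearman trend
  labels.
* **Integration** — peak-to-gene assignment within 2 kb of a TSS,
  alternative-promoter classes (pairs ≤ 100 kb), per-CpG methylation age
  tests with BH FDR, the histone/methylation anti-correlation 2×2 tested
  by hypergeometric upper tail, and generic over-representation with
  −log10(FDR) enrichment scores.
* **Synthetic cohorts** — a seeded generator planting the saturating
  kinetics (31 samples at the published cohort ages + input control)
  so every stage is validated against ground truth without external data.

## Worked example

```r
library(epitraject)

co     <- simulate_cohort(cohort_config(seed = 1))
prom   <- build_promoters(co$annotation)
chip   <- co$meta$sample_id[co$meta$fraction == "chip"]
dm     <- build_density_matrix(co$reads[chip], co$regions, prom)
groups <- assign_age_groups(co$meta$age_years[match(chip, co$meta$sample_id)])
calls  <- classify_up_down(dm, groups)
print(calls)
#> trajectory_calls: 2000 regions; 200 down, 100 up, 1700 unchanged
table(planted = co$models$klass, called = calls$klass)
#>        called
#> planted down none   up
#>    down  200    0    0
#>    flat    0 1700    0
#>    up       0    0  100
```

All 200 planted down-trajectory and 100 planted up-trajectory regions are
recovered with no false calls: the printed counts are the per-class sizes
of the classification, and the cross-table shows planted class against
called class. The hypergeometric anti-correlation worked example:

```r
hypergeometric_upper_tail(62, 394, 108, 1138)
#> [1] 2.968867e-07
```

— the probability that at least 62 of the 394 CpGs near up-trajectory
genes show decreased methylation when 108 of all 1138 CpGs do.

A full file-based run (simulate → quantify → callpeaks → structure →
trajectories → integrate → report):

```r
cfg <- pipeline_config(out_dir = "run1",
                       cohort = cohort_config(meta = reduced_cohort(),
                                              n_regions = 200, seed = 1))
run_pipeline(cfg)   # TSV/BED/JSON per stage + report.json
```

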