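# sampenmap

Voxelwise sample entropy mapping and group statistics for 4D fMRI.

Brain-entropy mapping treats the BOLD signal at each voxel as a time series
and asks how *irregular* it is. The irregularity statistic here is **sample
entropy** (SampEn): for a series `x = [x_1, ..., x_N]`, embed windows of
`m` consecutive points, count the pairs of windows whose Chebyshev (maximum
component) distance is within a tolerance `r`, do the same for windows of
length `m + 1`, and report

    SampEn(m, r, N, x) = -ln( A / B )

where `B` and `A` are the m- and (m+1)-window match counts over the common
template range `i = 1..N-m` (self-matches excluded). Lower values mean a
more regular, predictable signal. The defaults are the brain-mapping
convention: `m = 3` and `r = 0.6 * SD` of each voxel's own series.

The package is aimed at researchers studying BOLD signal complexity — e.g.
rest-vs-task entropy differences and their test-retest reliability. It
provides:

- **`sampen_core`** — `sample_entropy()`, `count_template_matches()`,
  `sample_entropy_map()` (compiled kernel; NA-with-reason sentinels for
  constant, short, or matchless series) and `truncate_bold()` for cutting
  rest scans to the task-scan length.
- **parcellation** — integer-label atlases (`atlas_labels()`,
  `read_atlas_nifti()`), per-region summaries (`roi_summary()`) and the
  scans-by-regions table (`build_cohort_table()`, `class_aggregate()`).
- **group statistics** — between-region Pearson correlation matrices across
  scans (`correlation_matrix()`), paired t-tests with Bonferroni correction
  (`paired_ttest()`, `bonferroni()`), balanced two-factor ANOVA with
  interaction (`two_factor_anova()`), and test-retest reliability via
  ICC(3,1) (`icc_3_1()`, `scan_consistency()`).
- **synthetic cohorts** — a seeded generator (`simulate_cohort()`,
  `simulate_cohort_table()`) that plants parcel-dependent AR(1) regularity,
  a rest/task condition effect, subject random effects and shared per-scan
  variation, with full ground truth for recovery tests.
- **pipeline** — `run_simulate()` → `run_map()` → `run_aggregate()` →
  `run_stats()`, plus a CLI at `inst/cli/sampenmap`.

## Worked example

Voxelwise entropy of one synthetic scan, summarised by region:

```r
library(sampenmap)
cfg    <- cohort_config(n_subjects = 2, seed = 1)
cohort <- simulate_cohort(cfg)
map <- sample_entropy_map(cohort$scans[[1]]$bold,
                          mask = cohort$atlas$labels > 0)
map
#> Entropy map 12 x 12 x 12: 576 defined voxels; undefined by reason:
#> short-series=0, zero-variance=0, zero-matches=0
roi_summary(map, cohort$atlas)
#>   label             name       class  mean     sd n_valid
#> 1     1           Visual    cortical 0.988 0.0417      64
#> ...
#> 8     8         Thalamus subcortical 1.059 0.0424      64
#> 9     9          Putamen subcortical 1.048 0.0436      64
```

Subcortical entropy exceeds cortical entropy because the generator gives
subcortical parcels a lower AR(1) coefficient (less temporal regularity).

The full statistical battery on a 100-subject cohort (parcel-level fast
path; 400 scans):

```r
res <- simulate_cohort_table(cohort_config(n_subjects = 100, seed = 7))
out <- run_stats(res$table, "stats_out")
out$table2[, c("network", "rest_mean", "task_mean", "mean_diff",
               "t_stat", "p_bonferroni")]
#>            network rest_mean task_mean mean_diff t_stat p_bonferroni
#> 1           Visual     0.957     0.877    0.0795   30.7     1.53e-76
#> 2      Somatomotor     0.936     0.846    0.0899   31.5     2.03e-78
#> ...
```

Every network shows rest entropy above task entropy (positive `mean_diff`,
Bonferroni-adjusted p over the 7-network family), recovering the planted
condition effect. `out$table3` holds the condition x class ANOVA,
`out$table5` the scan-1 vs scan-2 consistency (ICC(3,1) near 0.45 here —
moderate reliability, as configured), and `stats_out/` the CSV bundle with
the correlation matrices and a checksummed run report.

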