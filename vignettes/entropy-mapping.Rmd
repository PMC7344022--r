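---
title: "Methods: voxelwise sample entropy mapping and its group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxelwise sample entropy mapping and its group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sampenmap)
```

## The statistic

Sample entropy quantifies the irregularity of a time series by template
matching. For `x = [x_1, ..., x_N]`, windows of `m` consecutive points
`u_i = [x_i, ..., x_(i+m-1)]` are compared under the Chebyshev (maximum
component) distance; `B` counts ordered pairs `i != j` whose m-windows lie
within a tolerance `r` of each other, `A` the same for (m+1)-windows, and

$$\mathrm{SampEn}(m, r, N, x) = -\ln\frac{A}{B}.$$

Both counts run over the common template range `i = 1..N-m`. This choice
matters: with a common range every (m+1)-match is also an m-match, so
`A <= B` holds structurally and the statistic is guaranteed nonnegative.
The normalisation constants `1/((N-m)(N-m-1))` that appear in the
match-frequency definitions cancel in the ratio and are never materialised.
A periodic series (every m-match extends to an (m+1)-match) gives exactly 0;
an iid Gaussian series approaches the closed form
`-ln(2*pnorm(r_factor/sqrt(2)) - 1)` — about 1.113 at the default tolerance
— because window components are independent and the ratio collapses to the
one-step match probability. These two limits anchor the test suite.

### Parameters

- **`m = 3`** (embedding dimension). Small `m` keeps match counts high at
  fMRI series lengths (a few hundred points), which is what makes the
  estimator usable per voxel.
- **`r = 0.6 * SD(series)`** (tolerance). The SD is the *per-series* sample
  SD (`n - 1` denominator), computed on the series actually passed to the
  routine — i.e. after any rest-scan truncation. Per-series scaling makes
  the statistic invariant to affine rescaling of a voxel's signal, which is
  the property that lets entropy maps be compared across voxels with very
  different raw BOLD amplitudes. A fixed absolute tolerance is available
  via `sampen_params(sd_mode = "fixed")` for calibration work.
- **Distance**: Chebyshev, the Richman–Moorman convention; the match
  predicate is `d <= r`. For continuous data the boundary has probability
  zero, so `<` vs `<=` is immaterial in practice, but the contract is pinned
  for exactness tests.
- **Detrending**: off by default — entropy is computed on the series as
  given. A linear-detrend switch exists (`detrend = TRUE`) because slow
  drifts inflate the SD and hence the tolerance, but it is deliberately not
  the default: the mapped quantity should be the signal's, not a
  preprocessed surrogate's.

### Undefined values

Three degeneracies make the logarithm undefined: a series shorter than
`m + 2`, a constant series (tolerance `0.6 * 0 = 0`), and a series with no
m- or (m+1)-matches at all. All three return `NA` with a reason code rather
than a substitute number — substituting a ceiling value would bias every
region mean that contains such a voxel. Region summaries average defined
voxels only and report how many contributed; maps carry a parallel reason
lattice that round-trips through the NIfTI sidecars. Zero-match voxels are
the main silent failure mode of the statistic at short series lengths,
which is why the pipeline logs their tally per scan.

## From voxels to regions

Entropy is computed voxelwise first and averaged within each atlas parcel
afterwards (*mean of voxel entropies*). The alternative — entropy of the
parcel-mean signal — is a materially different quantity (averaging cancels
independent noise and lowers entropy) and is intentionally not offered under
the same name. Scan-level cortical/subcortical scalars are unweighted means
over the parcels of the class, treating each region as the observational
unit; a voxel-count-weighted variant exists behind
`class_aggregate(weight = "voxel")`. Cohort tables order rows deterministically
by (subject, condition, scan index) so that every downstream matrix is
reproducible bit for bit, and they round-trip losslessly through CSV at
full double precision.

## The inferential layer

- **Correlation matrices.** Entry (a, b) is the Pearson correlation between
  the per-scan mean entropies of regions a and b across all scans of a
  condition. Scans with any missing cell among the selected regions are
  dropped listwise, never pairwise: every entry then uses the same scan set
  and the matrix stays positive semidefinite.
- **Paired t-tests.** Rest and task scans are paired by
  (subject, scan index) — the only deterministic pairing the two-scans-per-
  condition design admits. Bonferroni families equal the set of
  simultaneous tests in each table (7 for the network table; 1 for the
  single whole-brain class contrast), and raw and adjusted p are always
  reported together. The subcortical-vs-cortical contrast is a paired t
  across scans on the class aggregates and is labelled as such in the
  output.
- **Two-factor ANOVA.** Condition x class (2 x 2) and condition x network
  (2 x K) on the per-scan aggregates, classical sum-of-squares partition
  with interaction. The designs are balanced by construction, which makes
  the Type I/II/III decompositions coincide; unbalanced input is rejected
  rather than silently re-weighted.
- **ICC(3,1).** Test-retest reliability is the two-way mixed, single
  measure, *consistency* intraclass correlation
  `(BMS - EMS) / (BMS + EMS)` from the subjects x scans decomposition
  (`k = 2`). The consistency form ignores a fixed shift between scan 1 and
  scan 2, which is the right behaviour for a repeatability question.
  The companion two-tailed p in the consistency table compares the scan-1
  and scan-2 means by paired t — the natural reading of a "two-tail"
  column next to ICC and r.

## The synthetic generator

The generator's purpose is a cohort whose *statistical structure* matches
what the analysis assumes, with full ground truth:

- **Complexity knob: AR(1) regularity.** Each parcel's voxels are
  independent AR(1) series; the coefficient `phi` controls regularity, and
  sample entropy is smoothly, monotonically decreasing in `phi`. The
  generator makes no claim to model hemodynamics — it is a statistical
  phantom, not a physiological one.
- **Effect structure.** Effective
  `phi = phi_base(condition) + subject_offset + scan_offset`, clipped to
  `[0, 0.98]` with clip events counted (erroring would let extreme random
  draws kill a simulation). The persistent subject offset creates
  test-retest reliability; the per-scan offset, shared by all parcels of a
  scan, creates the high between-region entropy correlations seen across
  scans; the condition shift `phi_task_delta >= 0` encodes rest entropy >
  task entropy.
- **Defaults as study conditions.** 405 time points (about 5 min at a
  0.72 s repetition time, the length rest scans are truncated to), two rest
  and two task scans per subject, seven cortical "network" parcels plus two
  subcortical parcels of 64 voxels each on a 12³ grid. Cortical `phi_rest`
  spans 0.55–0.68, subcortical 0.38–0.42 (subcortex less regular, hence
  higher entropy), `phi_task_delta = 0.1`. `subject_sd = 0.03` and
  `shared_scan_sd = 0.03` were set so the downstream structure lands where
  resting-state reliability studies typically find it — network ICC(3,1)
  around 0.45 (moderate) and between-network entropy correlations above
  0.9 — and are then left alone.
- **Entropy ground truth by reference curve.** Because effects act on
  `phi`, the expected entropy at a given `phi` is defined by a Monte-Carlo
  reference curve (`sampen_phi_curve()`, 200 series per point at N = 405),
  cached as a plain-text fixture under `inst/extdata/`. The fast cohort
  path (`simulate_cohort_table()`) draws a region mean as
  `curve_mean(phi) + N(0, curve_sd(phi)^2 / voxel_count)` — the sampling
  error of a mean over independent voxels — and is used where the
  statistics layer is under study; the full 4D path feeds the voxelwise
  kernel end to end.
- **Long-rest mode** (`rest_timepoints`) generates rest scans longer than
  task scans so the truncation step is exercised under realistic
  conditions.

**What passing tests do and do not show.** The phantom has no spatial
autocorrelation, no physiological noise, no motion, no hemodynamic response
and no tissue-dependent amplitude structure. Recovery of planted effects
therefore validates the *estimators and their wiring* — not robustness of
the statistic to real-data confounds such as motion-induced entropy changes
or preprocessing choices.

## Numerical and design notes

- Counts are accumulated over unordered pairs and doubled (symmetry), in
  compiled code; the test suite pins the production kernel against a
  definitional double-loop oracle exactly in counts and to 1e-12 relative
  error in entropy on 200 randomized series.
- Ties with the tolerance boundary cannot occur for the continuous
  generators used in testing; integer-valued fixtures avoid distances
  exactly equal to `r`.
- The parcel count is data-driven from the atlas everywhere; nothing
  assumes seven networks or any particular region count.
- The network-level tables treat the parcels of one designated class
  (default `"cortical"`) as "the networks", mirroring designs in which the
  canonical seven networks are cortical and subcortex is handled as a
  separate class.
- Degenerate statistics are reported as reasoned missing values, never as
  numbers: zero-variance paired differences, all-equal ANOVA responses,
  constant correlation inputs.
- Problem sizes in the test battery (e.g. 500 parcel-level null cohorts of
  50 subjects; one full 4D directional cohort of 20 subjects on a 12³
  grid; 100-replicate ICC recovery at 200 subjects) were chosen as the
  smallest sizes at which the checked properties have tight sampling
  distributions.
- Pipeline stages communicate through on-disk artifacts with a checksummed
  inventory and the config hash and seed in every run report, so any
  output can be traced to the exact configuration that produced it; a
  mapping stage refuses to overwrite existing outputs unless forced.

## Known limitations

Single-scale SampEn only (no multiscale or fuzzy variants); volumetric
analysis only; hard label atlases only; no FDR or permutation-based
multiplicity control; the ANOVA layer requires balanced designs by
contract. The absolute-agreement ICC(2,1) is out of scope — the
reliability question here is consistency.
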