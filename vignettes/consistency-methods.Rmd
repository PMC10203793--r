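---
title: "Quantifying test–retest consistency of white-matter measure maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying test–retest consistency of white-matter measure maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmconsist)
```

## The problem

A white-matter measure is useful as a longitudinal biomarker only if
re-scanning the same person yields nearly the same value, while different
people remain distinguishable. `wmconsist` quantifies both aspects for
voxel-wise measure maps (diffusion- or myelin-based) evaluated over
bundle-shaped masks, across a cohort of subjects scanned repeatedly:

- *reliability*: the share of total variance attributable to stable
  between-subject differences (an intraclass correlation);
- *reproducibility*: within-subject variability across sessions (CVw);
- *heterogeneity*: between-subject variability of session-averaged values
  (CVb).

All inputs are assumed to live on one common grid (a population template
space); the package neither registers nor resamples images.

## The model and the I2C2 estimator

Write the vectorized map of subject $i$, session $j$ over the analysis mask
as $W_{ij}$. The implicit one-way random-effects model is

$$W_{ij}(v) = \mu(v) + X_i(v) + U_{ij}(v),$$

with subject effect $X_i$ (variance $\sigma_b^2$ per voxel) and
session-level error $U_{ij}$ (variance $\sigma_w^2$). The image intraclass
correlation coefficient is the variance ratio
$\lambda = \sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$ generalized to images via
traces of the between- and total-covariance operators. `i2c2()` uses the
method-of-moments trace-ratio estimator

$$\hat\lambda = 1 - \frac{T_w}{T_t}, \qquad
T_w = \frac{\sum_{ij} \lVert W_{ij} - \bar W_i \rVert^2}{N - I}, \quad
T_t = \frac{\sum_{ij} \lVert W_{ij} - \bar W \rVert^2}{N - 1},$$

with $N$ records and $I$ subjects. Design choices worth making explicit:

- The $(N-I)$ and $(N-1)$ degrees-of-freedom scalings make the estimator
  well defined for unbalanced designs (subjects may have different session
  counts) and reduce it to the classical scalar one-way ICC with
  total-variance denominator on single-voxel images — the property the test
  suite checks against an `aov()` oracle to $10^{-10}$.
- $\hat\lambda \le 1$ always; it can be negative in degenerate data. If all
  records are identical ($T_t = 0$) the value is defined as 1 with a
  warning.
- The estimator is a ratio statistic and carries a finite-sample negative
  bias; at a balanced $20 \times 5$ design and $\lambda = 0.5$ the bias is
  about $-0.026$ (measured by simulation), driven partly by
  $E[T_t] = \sigma_b^2 (N - J)/(N - 1) + \sigma_w^2$ and partly by the
  nonlinearity of the ratio. Parameter-recovery tests use tolerances that
  account for exactly this behaviour; no attempt is made to bias-correct,
  since the published quantity is the plain trace ratio.

### CVw and CVb

`cv_within()` computes, per subject, the sample CV of that subject's session
values (SD with denominator $n-1$, divided by the subject mean) and averages
across subjects. `cv_between()` first averages each subject session-wise and
takes the CV of those averages. Both are reported in percent and require
positive means. For voxel-level analysis cells the CVs are computed on the
per-record *spatial means* of the densified cell: whether the original
analyses took scalar or voxelwise CVs is ambiguous, and the spatial-mean
convention keeps CVs interpretable on the measure's natural scale while
using exactly the voxels that enter the I2C2.

### Bootstrap inference

`bca_bootstrap()` resamples *subjects* with replacement — all sessions of a
subject move together, preserving the within-subject correlation structure
that the statistics measure. Intervals use the accelerated bias-corrected
percentile method: bias correction $z_0 = \Phi^{-1}(\#\{\theta^* <
\hat\theta\}/B)$ and acceleration $a$ from the skewness of
leave-one-subject-out jackknife values. The p-value is the smallest
$\alpha'$ (grid resolution $1/B$) at which the $(1-\alpha')$ interval
excludes 0. Defaults: $B = 2000$, $\alpha = 0.05$.

`i2c2_bca()` computes the identical quantity (same resampling stream, same
estimator) from per-subject sufficient statistics — subject sum-images, their
Gram matrix, squared norms and within-subject sums of squares — so that each
replicate costs $O(I^2)$ independent of the voxel count. The test suite
asserts the two paths agree on the same seed.

Two empirical facts about these intervals, established by the package's own
simulations and worth knowing before relying on them: (i) the implementation
reproduces an independent BCa implementation's endpoints to within bootstrap
noise; (ii) at $I = 20$ subjects the 95% interval for the I2C2 covers the
true variance ratio in roughly 89–90% of replicates rather than 95%. This
undercoverage is characteristic of nonparametric bootstrap intervals for
skewed variance-ratio statistics at small subject counts (the same
implementation covers at ~93% for a sample mean at $n = 20$ and ~86% for a
sample SD), so the intervals should be read as slightly anti-conservative.

## Masks, sections, compartments, QC

The mask pipeline mirrors how tractometry studies prepare analysis regions:

- `binarize_density()` thresholds a streamline-density map (strictly
  positive by default; the threshold is a parameter because no canonical
  cutoff exists).
- `erode_mask()` produces the "safe mask" with one 6-connected erosion —
  the face-adjacency structuring element is the most conservative
  single-voxel shell, chosen because partial-volume contamination is a
  surface phenomenon.
- `split_sections()` intersects ten equidistant along-bundle section labels
  with the safe mask; `merge_lr()` unions hemispheric masks.
- `compartmentalize()` splits a mask into single- (NuFO = 1) and
  multi-fiber (NuFO ≥ 2) compartments; NuFO = 0 voxels drop out.
- `apply_volume_qc()` excludes units whose *mean volume across records*
  falls strictly below 1000 voxels (sections) or 400 voxels
  (compartments); a unit exactly at the threshold is kept. The mean across
  records (not the per-record volume) is the tested quantity because
  exclusion is a property of the unit, not of a session.
- `threshold_isovf()` invalidates (sets to `NaN`, never clips) ISOvf values
  below 0.045; invalid voxels are excluded from every downstream statistic.

Compartmentalization happens before QC: each (section × compartment) unit is
tested against the compartment threshold after the split. The ordering is a
package choice; the alternative (QC on sections first) would keep slightly
more compartment cells.

## Densification over mask unions

Per-session masks never overlap perfectly. Voxel-level statistics are
computed over the voxelwise *union* of all record masks; `union_and_densify()`
imputes a voxel missing from record $r$ with the mean over the records that
observe it, preferring the same subject's other sessions when at least one
observes the voxel and falling back to the whole cohort otherwise. The
subject-first precedence is a package choice (either pooling order is
compatible with "the available subjects or sessions"); it keeps imputed
values centred on the subject's own level and therefore perturbs the
between-subject variance less. Voxels observed nowhere are dropped; an
imputation fraction above 50% triggers a warning. With fully overlapping
masks the whole step is bit-for-bit a no-op — a tested invariant.

Imputation by observed means necessarily *shrinks* apparent within-record
variability: heavily jittered masks push the I2C2 of the densified matrix
above the population variance ratio of the underlying measure. This is a
property of the densification procedure itself, visible in the acceptance
outputs (the default jittered cohort estimates ~0.90 for a measure whose
population ratio is 0.862), and is the reason parameter-recovery experiments
run with unjittered masks.

## The synthetic cohort generator

No generative model is published for this kind of data; the generator exists
so that estimators can be validated against known ground truth, and its
distributional choices are exactly the assumptions of the one-way model:

$$W_{ij}(v) = \mu + T(v) + X_i + U_{ij},$$

with a *fixed* spatial texture $T$ (SD $\sigma_v$, optionally
Gaussian-smoothed with a stated FWHM in voxels; FWHM 0 means white noise)
and spatially constant subject/session effects. Spatially constant effects
keep the closed-form truth $\lambda = \sigma_b^2/(\sigma_b^2+\sigma_w^2)$
available; they also mean the generator does **not** emulate spatially
heterogeneous reliability, scanner drift, registration error, or
measure-specific noise floors — passing recovery tests validates the
estimators under the model, not the MRI physics.

The geometry is a straight cylinder (radius and length in voxels) split into
`n_sections` equal slabs (remainder slices to the last section). Per-session
masks flip boundary voxels (inner surface and outer shell, 6-connectivity)
independently with probability `mask_jitter`, which drives expected Dice
down monotonically — the handle used to emulate segmentation variability.
NuFO maps assign each in-mask voxel 1 fiber population with probability
$1 - p_{multi}$ and 2 or 3 otherwise (equal split); the default
$p_{multi} = 0.78$ sits mid-range of the reported 66–90% prevalence of
multi-fiber voxels in white matter. Density maps are a radial taper plus
small noise, supported on each record's mask.

Defaults describe the reference design: 20 subjects × 5 sessions, a
~12,750-voxel bundle (radius 9, length 50) whose ten sections each clear
the 1000-voxel QC threshold, `mask_jitter = 0.1` (mean Dice ≈ 0.95), and
three measures spanning the reliability range typically reported for
diffusion and MT measures: FA-like ($\mu = 0.5$, $\lambda \approx 0.86$),
ISOvf-like ($\mu = 0.06$, $\lambda \approx 0.57$, low mean so the 0.045
cutoff is exercised) and ihMTR-like ($\mu = 10$, $\lambda \approx 0.43$).
Everything is deterministic given the seed, and cohorts round-trip through a
`sub-XX/ses-YY/*.nii.gz` NIfTI layout (written in float64 by default so the
round trip is exact).

## Numerical and design choices

- Sample SDs use denominator $n - 1$ throughout.
- Correlation matrices average per-session Pearson r entrywise
  (arithmetic mean); Fisher-z averaging is available behind a flag. Sessions
  with zero variance for a measure are omitted for the affected pairs.
- Between-measure correlations and bundle means use the safe
  (one-voxel-eroded) mask by default, consistent with the consistency
  analyses; Dice and density correlation use the raw segmentation masks,
  since they evaluate the segmentations themselves.
- Empty ∩ empty Dice is 1 by convention (agreement on absence), with a
  warning.
- The pipeline derives per-stage seeds from one config seed by a fixed
  counter scheme (simulation uses the seed itself, the bootstrap of cell $k$
  uses seed + 1000 + $k$), so any stage can be reproduced in isolation and
  reruns write byte-identical tables.
- Validation experiments in the test suite run at deliberately modest sizes
  (bundles of ~350–1030 voxels, 50–200 replicate seeds) chosen so the whole
  suite completes in about a minute while keeping Monte-Carlo error well
  below the asserted tolerances; the null-correlation check simulates
  measures at $\lambda = 0.25$, where the analytic null sampling variance of
  session-averaged r is smallest, making the check well calibrated.

## Known limitations

- The generator's spatially constant effects make voxels exchangeable;
  estimator behaviour under strong spatial heterogeneity is untested.
- BCa intervals at 20 subjects undercover by ~5 points (see above); studies
  needing calibrated intervals at this scale should consider more subjects
  or interval methods beyond the scope of this package.
- Densification biases I2C2 upward when mask overlap is poor; report the
  imputed fraction (the tables carry it) alongside any estimate.
- No streamline-level operations: section labels come from geometry (or are
  supplied as label maps), not from resampling tractograms, and the
  streamline-adjacency reproducibility metric is out of scope.
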