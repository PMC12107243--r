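---
title: "Voxel-wise graph metrics for resting-state connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise graph metrics for resting-state connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelgraph)
```

## The model

voxelgraph treats each subject's resting-state acquisition as a graph whose
nodes are in-mask voxels and whose edge weights are nonnegative Pearson
correlations between voxel time series. Three per-voxel maps summarize the
graph:

* **weighted degree** — `WD_i = sum_j adj(i, j)`, the total edge weight of
  voxel *i* over the whole-brain matrix. A centrality measure: how strongly
  a voxel is coupled to the rest of the brain.
* **integration** — the same sum restricted to voxels *j* assigned to a
  *different* network than *i*, indexing between-network communication.
* **segregation** — the sum restricted to same-network voxels, indexing
  within-network communication.

Network assignment uses a seven-network isocortical parcellation (visual,
somatomotor, dorsal attention, ventral attention/salience, limbic,
frontoparietal, default mode); integration and segregation are therefore
computed on the isocortex-restricted matrix only, while weighted degree uses
the whole-brain matrix. Because integration and segregation partition the
same set of edges, for every isocortical voxel

```
integration_i + segregation_i = weighted_degree_i (isocortical matrix)
```

holds exactly; the test suite asserts this identity to 1e-12 over hundreds
of random matrices.

Two modelling conventions are worth making explicit. Negative correlations
are set to zero rather than dropped from the edge list, keeping the matrix
rectangular so that the metric sums stay well defined. The diagonal is
forced to zero: including the self-correlation of 1 would add the same
constant to every voxel and carry no information.

## Denoising chain

The per-subject chain is fixed: confound regression, then zero-phase
band-pass filtering, then scrubbing and volume selection. Deleting scrubbed
volumes *after* filtering avoids propagating filter transients across
gaps; the alternative order (scrub, then filter on a resampled grid) is a
legitimate choice in some pipelines but changes results, so the order here
is asserted by a regression test.

* **Confounds.** The design contains an intercept, the six rigid-motion
  parameters and their first differences, linear and quadratic trends, and
  five principal components from each designated noise-tissue voxel set (a
  compcor-style emulation; in synthetic cohorts the "lateral ventricle" and
  "white matter" sets are two halves of the label-0 voxels, since tissue
  segmentation is out of scope). Constant columns are dropped silently;
  genuinely collinear columns are dropped with a warning.
* **Band-pass.** Fourth-order Butterworth, 0.01-0.08 Hz, applied forward
  and backward for zero phase with odd-reflection padding of
  3 x (filter length - 1) samples. The normative contract is the frequency
  response (pass band within ±10%, ≥90% attenuation at 2x the upper edge,
  zero phase), not the filter family. The recursion is vectorized across
  voxels and verified against the reference single-series IIR filter.
* **Scrubbing.** Framewise displacement uses the Power convention with a
  50 mm rotation radius (the source analysis states no convention; 50 mm is
  the field default). The threshold comparison is strict (> 0.5 mm), so an
  FD of exactly 0.5 survives. Only the volume terminating a high-FD
  transition is removed — no neighbour augmentation.
* **Volume selection.** Runs are concatenated after scrubbing and the first
  120 surviving volumes are retained, so every subject contributes equally
  to the correlation estimates; subjects with fewer than 120 usable volumes
  are excluded with reason `"motion"`. There is no third outcome.

## Normalization and QC

Subject exclusion is two-stage and order-sensitive: motion exclusions are
applied first, then subjects whose mean whole-brain weighted degree falls
outside Tukey fences at 1.5 IQR (type-7 quartiles, strict comparison,
pooled over all remaining subjects) are excluded as outliers.

Before group contrasts, age and sex effects are removed per voxel by OLS
and every map is z-scored against the healthy-control (HC) per-voxel mean
and sample SD (n − 1 denominator). The residualization is fitted on the
pooled sample: the stated order of operations ("remove the effect of age
and sex, then normalize") implies a single covariate model over
participants before HC statistics are taken, and pooled fitting keeps the
HC mean/SD interpretable. Fitting on HC only and applying to everyone is
available behind `fit_on = "HC"` for sensitivity analyses. Sex is coded
0/1; zero-SD voxels are flagged and zeroed rather than producing
infinities.

## Group inference

Per voxel, an OLS of the normalized value on
`[1, group indicator, covariates]` yields a t-statistic mapped to z through
the t-to-z quantile transform at the residual degrees of freedom. The
default covariate is antidepressant (SSRI/SNRI) use; age and sex are
already removed. HC subjects define the normalization only and never enter
contrasts.

Clusterwise correction is Monte Carlo: the null distribution of the maximum
suprathreshold cluster extent is estimated by permuting group labels across
the contrasted subjects (covariates stay attached to their subjects) and
refitting the GLM exactly on each permutation, via the Frisch-Waugh-Lovell
identity, in compiled code. This choice — permutation rather than
smoothness-matched Gaussian-field simulation — is deliberate: it is
data-adaptive, requires no estimate of intrinsic map smoothness, and is
exact under exchangeability. Parameters follow the published convention:
cluster-forming |z| > 1.96, two-sided with sign-separated clusters (both
increases and decreases are reported), 26-connectivity (configurable to 6),
10 000 iterations by default, alpha 0.05, and the +1 convention
`p = (1 + #{null max >= extent}) / (1 + n_iter)` so corrected p-values are
never zero. Clusters and the null must carry identical threshold /
sidedness / connectivity parameters or correction refuses to run.

Under a global null this machinery is calibrated: over 500 simulated null
cohorts (30 vs 30 subjects, 12x12x12 grid, 1000 iterations) the probability
that any cluster survives correction is measured at ~0.05 by the acceptance
suite.

## Seed analysis and symptom correlations

Seeds are placed at the per-hemisphere peak z of the integration contrast,
restricted to voxels surviving correction (and, when supplied, the
intersection mask across post hoc adjustments). Hemispheres split at the
grid midline; argmax ties break to the lowest voxel index so results are
deterministic. The ROI is the 3x3x3 voxel neighbourhood of the peak — the
printed member count of 27 voxels is treated as normative, since a
Euclidean 3 mm ball on a 3 mm grid would contain only 7 voxels. Edge seeds
are kept (not recentred) and simply have fewer members.

Seed maps are Fisher r-to-z transforms of the correlation between the mean
seed series and every isocortical voxel, with |r| clipped at 1 − 1e−7
before `atanh`. The group contrast reuses the full clusterwise machinery;
significant *positive* voxels are then decomposed by network, excluding the
seed's own network from numerator and denominator (those connections are
not integration-relevant; positive-only counting follows the direction of
the reported effects). When seed members straddle networks, the peak
voxel's label defines the seed network.

Cluster-mean symptom correlations are Spearman with mid-ranks, p from the
t approximation at n − 2 df (exact permutation available for n ≤ 10),
computed for the documented cohort pairings: both symptom scales within the
FND cohort, the somatic-symptom scale only across FND + PC. Outlier removal
at 1.5 IQR is applied to the connectivity variable only — the outlier rule
is stated for metric values, not symptom scores — per cluster, metric and
cohort pairing. FDR control is Benjamini-Hochberg within (cohort pair,
metric) families.

## The synthetic cohort generator

No imaging data ship with the package; the generator produces cohorts with
the statistical structure the analysis assumes, so every stage is testable.

* Voxel time series are multivariate normal draws whose correlation matrix
  has `base_within_corr` (default 0.3) on within-network pairs and
  `base_between_corr` (default 0.1) on between-network pairs — values in
  the range typical of band-passed resting-state data — plus independent
  observation noise (`noise_sd` 0.2, attenuating correlations by
  ~1/(1 + sd^2) ≈ 4%). Network blocks come from a recursive-bisection
  parcellation into contiguous boxes, with ~10% of the mask labelled 0 to
  exercise the whole-brain versus isocortex distinction.
* Effects add `delta_corr` to chosen edges: between-network edges,
  within-network edges, or all edges incident to a target region, for a
  target group, optionally scaled by a subject covariate
  (`delta + slope * (covariate − group mean)`). Because naive addition can
  break positive-definiteness, targets are repaired by Higham-style
  nearest-PD projection (`Matrix::nearPD`) with a logged warning — this
  keeps effect sizes interpretable as correlations.
* Motion is a gentle random walk (SD 0.02 mm per step) with sustained
  0.8 mm translation steps as scrub-worthy events; rotations are held at
  zero, which keeps the FD arithmetic simple while still exercising
  scrubbing. Default acquisitions are 160 volumes at TR 2 s so that two
  spikes still leave ≥120 usable volumes.
* Everything is deterministic given the config seed; each subject's draw is
  seeded by (config seed, subject index), so single subjects are
  reproducible in isolation.

What the generator does **not** emulate — haemodynamic autocorrelation,
spatial noise correlation, physiological confounds, scanner drift beyond
polynomial trends, multi-site effects — bounds what passing tests show:
they validate the statistical machinery under the stated covariance model,
not robustness to every artefact of real acquisitions.

## Numerical choices and problem sizes

* Correlation matrices are computed from standardized series by cross
  products; an optional column-block path bounds memory for larger masks
  and is bit-compatible with the dense path.
* The t-to-z transform works on log-scale tail probabilities, keeping
  extreme statistics finite and monotone.
* Quartiles are type 7 (linear interpolation) everywhere an IQR rule
  appears; both outlier rules use strict comparisons, so zero-spread data
  exclude nobody.
* Argmax ties (seed peaks) break lexicographically by voxel coordinate.
* Test and acceptance problem sizes were chosen once as desk-scale versions
  of the study design: 12x12x12 grids (1728 voxels), 30 subjects per group,
  120 retained volumes, 1000 permutation iterations for calibration
  studies and 500 replicate simulations for error-rate estimates. The
  published parameters (0.5 mm FD, 120 volumes, 0.01-0.08 Hz, |z| > 1.96,
  10 000 iterations, alpha 0.05) are the package defaults.

## Known limitations

* Permutation inference assumes exchangeability of subjects under the null
  within the contrasted groups; strong covariate imbalance is handled by
  adjustment, not by restricted permutation blocks.
* The generator's white temporal spectrum means band-pass filtering reduces
  effective degrees of freedom in synthetic data slightly differently than
  for real, autocorrelated series.
* The parcellation is hard (one network per voxel); overlapping or dynamic
  network structure is out of scope, as are TFCE and voxel-wise FWE/FDR
  alternatives to clusterwise correction.
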