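---
title: "Lesion-aware denoising for stroke rs-fMRI: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-aware denoising for stroke rs-fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokefc)
```

## The problem

Resting-state functional connectivity is estimated from temporal
correlations between regional BOLD signals. In stroke patients this
estimate is doubly fragile: the lesion itself is non-functional tissue
whose signal is dominated by vascular and pulsatile artifacts, and
perilesional hemodynamics are delayed, so that ordinary nuisance models
built for healthy brains leave *spurious connectivity* — strong
correlations between dead tissue and intact cortex — in the data.
`strokefc` implements a lesion-aware confound model downstream of
conventional preprocessing (all images already co-registered on one voxel
grid), three denoising presets that differ only in how they treat the
lesion, and the statistics used to compare them.

## Confound model

For a run of $T$ volumes the full nuisance set comprises:

* **Motion (24 columns).** The six rigid-body parameters, their backward
  temporal differences (first row imputed with 0 so design matrices stay
  NaN-free), and the squares of both.
* **Framewise displacement.** Power's formulation
  $\mathrm{FD}_t = \sum |\Delta d_t| + r \sum |\Delta \theta_t|$ with head
  radius $r = 50$ mm, and Jenkinson's
  $\sqrt{r^2/5\,\mathrm{tr}(M^\top M) + \lVert t \rVert^2}$ for the
  relative affine between consecutive frames ($M$ = rotation part minus
  identity), i.e. the RMS displacement over a solid 50 mm sphere.
* **DVARS.** RMS over brain voxels of the temporal difference signal;
  the standardized variant divides by the within-run median so that
  "1.5 standardized DVARS" means 1.5 times the typical frame-to-frame
  change. Frames with FD > 0.5 mm *or* standardized DVARS > 1.5 (strict
  inequalities) are annotated as motion outliers; they are not scrubbed
  by default.
* **Tissue signals.** Mean time series over the whole brain (the global
  signal) and over CSF and WM noise masks: probability maps binarized at
  0.99, minus a one-voxel (6-connectivity) dilation of the GM mask so no
  voxel with a GM fraction contributes. GS, WM and CSF all receive the
  same 4-fold expansion as motion (expansion of WM/CSF is a toggle).
* **aCompCor.** Voxel series inside the combined CSF+WM mask are
  high-pass filtered by regressing out a discrete-cosine basis (periods
  ≥ 128 s), variance normalized, and decomposed by SVD; the smallest
  number of leading components reaching 50% cumulative variance is
  retained. A run shorter than the cutoff period gets no cosine columns
  (with a warning).
* **Lesion adjustment.** In the `lesion_adjusted` variant the lesion is
  forced into the CSF mask, removed from the WM mask and from the
  GM-dilation exclusion; lesion-split mean signals (within-lesion,
  excluding-lesion, including-lesion) are emitted for QC. The
  within-lesion mean is *not* used as a regressor by any preset.
* **ICA-lesion regressors.** Spatial FastICA (logcosh contrast, symmetric
  decorrelation, implemented in-package) on the in-brain data; each
  component's spatial map is z-scored and binarized at $|z| \ge 2$; a
  component is flagged as lesion noise when the fraction of its
  suprathreshold voxels inside the lesion is ≥ 5% (the
  component-referenced denominator; a lesion-referenced option exists).
  Flagged mixing time courses become confound columns; the empty set is
  legal and reduces `ICLesionCompCorGS` to `CompCorLesionGS` exactly.

### ICA dimensionality

The default is `n_components = min(8, T %/% 5)`, deliberately small.
Components that fit unstructured noise have spatially near-uniform
suprathreshold sets, so their lesion overlap fluctuates around the
lesion's share of the brain (a few percent); with a 5% flag threshold such
components false-flag in a large fraction of runs. Keeping the model order
at or below the number of strongly structured sources makes every retained
component signal-bearing and drives chance overlap to zero. For long runs
with richer structure the order should be raised (`n_components`
argument). Mixing time courses are estimated by least squares on the
z-scored maps (the dual-regression convention).

## Hemodynamic lag and the QC gate

Lag mapping band-passes the data to 0.009–0.09 Hz, builds a gray-matter
reference (GM probability ≥ 0.5, lesion excluded), and for each voxel
finds the shift in ±4 TRs that maximizes the overlapping-sample Pearson
correlation with the reference; positive lags mean the voxel is delayed.

Two estimator choices deviate from the obvious textbook versions, for
cause:

* **Filter realization.** The band-pass is a zero-phase
  Butterworth-*magnitude* response applied in the frequency domain,
  default order 4. A forward–backward time-domain Butterworth of order 2
  cannot simultaneously keep 0.05 Hz within 5% (it loses 8.7%) and
  attenuate 0.2 Hz by more than 90% at TR = 2 s (single-pass order 2
  manages only 80%); order 4 magnitude satisfies both (99.6% kept,
  95.9% rejected) and is exactly zero-phase.
* **Sub-TR resolution.** With `subsample = TRUE` the search runs on a
  dense grid of TR/4 steps using Fourier-shifted references, rather than
  a three-point parabola. When the reference is a mixture of lag
  populations, the correlation profile has merged maxima; a parabola
  through integer samples systematically undershoots, the dense grid
  does not.

**Identifiability and the exclusion rule.** Against a global reference
only *relative* lags are identifiable: a delay shared by a large tissue
fraction is partially absorbed into the reference itself. In a real
cohort most GM is normally perfused, so the unaffected hemisphere sits at
lag ≈ 0 and "mean lag of the affected hemisphere" is well defined. At toy
scale the two hemispheres are symmetric, so the QC gate uses the
*affected-hemisphere excess* — mean affected lag minus mean unaffected lag
— which coincides with the conventional reading in real data and removes
the reference bias in the synthetic world. A subject is excluded when the
excess is above 1 s (signed lags by default; an absolute-value option
exists). Both raw hemispheric means are always reported. Even so, a
hemisphere-wide 1.5 s injection is measured as an excess of ~1.1–1.4 s:
the bimodal reference merges the two lag populations and compresses the
scale by roughly 20%. This attenuation is a property of
global-reference lag mapping, not of the implementation.

## Denoising and connectivity

Each preset assembles one design matrix — intercept, cosine drift, the
24 motion columns, expanded GS (unless GSR is disabled), expanded WM/CSF,
aCompCor components, plus the ICA-lesion group for `ICLesionCompCorGS` —
prunes collinear columns by QR, and removes everything in a single
least-squares regression. Because regression and spatial averaging
commute, denoising region means equals averaging denoised voxels; the
package uses the ROI route for connectivity and the voxel route for
lesion seed-to-voxel maps. No extra temporal filtering is applied after
regression (low-frequency control lives in the cosine columns, avoiding
filter–regression mismatch).

Connectivity is the Pearson correlation of region means with the
Ledoit–Wolf shrinkage covariance estimator: columns are standardized, the
shrunk covariance (scaled-identity target, analytic shrinkage intensity)
is computed and renormalized to unit diagonal. The implementation matches
`sklearn.covariance.ledoit_wolf` to 10 decimal places, shrinkage
included. One behavior worth knowing: on *uncorrelated* data the
scaled-identity target equals the truth, so the optimal shrinkage tends to
1 and Ledoit–Wolf correctly reports near-zero correlations even when the
sample correlations are ±0.02; agreement with sample Pearson at large $T$
is therefore a property of *correlated* data.

## Evaluation metrics

* **Positive / negative mean strength.** For each region overlapping the
  lesion (any nonzero overlap by default), the sum of its positive
  (negative) edges to all other regions; the statistic is the mean over
  lesion regions, the negative variant reported as a signed number.
  Positive minus |negative| equals the signed total strength
  (conservation identity, tested).
* **FCC.** The Wilcoxon rank-sum Z (normal approximation, tie and
  continuity corrected) comparing within-network against between-network
  edges, positive when within-network edges are stochastically larger.
  As a rank statistic it is invariant under monotone transforms of the
  edge values.
* **Q.** Louvain community detection on the positive-edge graph (negative
  edges zeroed) with 10 seeded restarts, best Newman weighted modularity
  kept; deterministic given the seed.

## The synthetic world

`generate_subject()` emulates exactly the inputs the pipelines consume,
at toy scale (24×24×12 voxels at 3 mm, 150 volumes at TR = 2 s, 20
regions in 4 networks):

* An ellipsoidal brain with smooth radial tissue probabilities (WM core,
  GM shell, CSF rim) and a k-means GM parcellation.
* Latent signals are *flat-band-spectrum random-phase* series in
  0.009–0.09 Hz. Filtered white noise is not used: its realizations
  randomly concentrate energy at the lowest band frequencies and become
  too smooth to resolve 1-TR lags even without noise.
* Each region's signal is
  $\sqrt{w_0}\,g_0 + \sqrt{r_w - w_0}\,g_{net} + \sqrt{1 - r_w}\,e_r$
  with within-network correlation target $r_w = 0.6$ and a global
  (vascular) share $w_0 = 0.4$. The global component is what a
  lagged-cross-correlation reference latches onto; its price is a
  between-network correlation of $w_0$ before GSR (which is also
  realistic — raw region correlations are strongly global-signal
  driven). Region/network-unique signals are sample-orthogonalized
  against the ±4 TR shift families of the shared signals so that
  ground-truth lag recovery is not corrupted by finite-sample
  cross-correlations at $T = 150$.
* Voxels get lognormal amplitude heterogeneity (SD 0.4 in log space),
  applied to signal and noise alike so voxel SNR is constant. Without
  it, the dense global/physio source maps are bimodal indicators —
  sub-Gaussian — and tanh FastICA fails to converge (verified with
  scikit-learn as an independent oracle).
* The lesion is either an exact-count nearest-voxel ball or the union of
  whole parcels (`lesion_covers_regions`), placed in the affected
  hemisphere. Lesion tissue is dead: no neural signal, uniformly
  attenuated noise (0.25× SD), plus a band-limited artifact time course
  of amplitude `a_les` (default 2 SD units). The same artifact is
  injected into remote *contaminated* regions chosen from networks the
  lesion does not belong to — the mechanism that manufactures spurious
  lesion connectivity across functionally unrelated areas.
* Lags are injected by exact circular Fourier shift of the whole neural
  signal, per region (`lag_by_region_trs`, integer TRs by default so
  discrete recovery is exact) or per hemisphere (`lag_affected_s`).
* Motion is a random walk (0.02 mm/frame) with occasional 0.3 mm spikes.

What the generator does *not* emulate: hemodynamic response shapes,
scanner noise spectra and drifts beyond the modelled bands, susceptibility
artifacts, spatial autocorrelation of noise, partial-volume mixing. A
green test therefore establishes that the estimators recover *this*
stated world's ground truth and match their independent oracles — not
that any clinical effect size is reproduced.

## Numerical choices

* Voxel indexing is 0-based; no resampling is implemented — inputs must
  share one grid (checked with 1e-4 affine tolerance).
* The hemispheric split uses world-x from the affine (x < 0 = left).
* Collinear design columns are dropped by QR pivoting with a warning.
* FastICA retries up to 3 derived seeds on non-convergence, then errors.
* Zero-variance series yield NaN lags; first-frame FD/DVARS are 0.
* All randomness flows from explicit integer seeds; identical seeds give
  bit-identical subjects, ICA flags and modularity values.

## Known limitations

* **ICA cannot beat lesion-aware CompCor at ROI level in a coherent
  synthetic world.** The `CompCorLesionGS` design already spans every
  coherent lesion time course (the lesion sits inside the aCompCor mask
  and the 50% variance rule retains its components), so at region level
  the ICA step has nothing left to remove; its regressors' estimation
  impurity slightly *inflates* the dead regions' positive noise floor
  (~+0.04 here). Substituting the ground-truth artifact course flips the
  difference negative, confirming the mechanism is implemented correctly.
  The corresponding acceptance clause (mean strength of
  `CompCorLesionGS` ≥ `ICLesionCompCorGS`) is left failing by design
  rather than gamed; the reductions of both lesion-aware pipelines
  against `CompCorGS` (the substantive effect) are large and
  sign-test significant.
* Hemisphere-wide lag injections are attenuated ~20% by reference mixing
  (see above); the QC gate margins account for it.
* The minimal NIfTI-1 reader handles single-file `.nii(.gz)`, 3D/4D,
  common datatypes and sform/qform affines — not extensions, CIFTI or
  multi-file pairs.
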