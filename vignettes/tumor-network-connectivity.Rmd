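---
title: "Tumor-to-network functional connectivity: model, estimator and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-to-network functional connectivity: model, estimator and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diffusely infiltrating gliomas can remain functionally coupled to the brain's
large-scale resting-state networks, and the degree of preserved coupling is a
candidate prognostic imaging biomarker: patients whose metabolically active
tumor region shows stronger functional connectivity (FC) to certain networks
tend to live longer.  `gliomafc` implements the full measurement chain for
this biomarker — from a patient's co-registered resting-state BOLD series,
amino acid PET volume and structural lesion masks down to hazard ratios for
overall survival — together with a synthetic data generator that plants every
quantity of interest, so that each stage can be validated against known
ground truth.

The package deliberately starts *after* scanner-side preprocessing: motion
correction, outlier removal, slice-timing and spatial normalization are
assumed done (synthetic data never need them).  All volumes of one subject
must share a single voxel grid and voxel-to-world affine.

## Tumor definition on PET

The metabolically active tumor is defined on amino acid PET via standardized
tumor-to-brain ratios (TBR): every voxel's activity is divided by the mean
activity of the *unaffected* brain, and voxels with TBR of **1.6 or more**
(inclusive) form the PET tumor mask.  The reference region is the brain mask
minus the composite lesion dilated by one voxel; the dilation guards the
reference mean against partial-volume spill-over at lesion borders.  Because
the composite lesion itself contains the PET mask, `run_subject()` uses two
passes: a provisional TBR image normalized outside the dilated *structural*
lesions yields a provisional PET mask, and the definitive TBR image is then
normalized outside the dilated full composite.  On noiseless synthetic data
the two passes agree exactly; on noisy data the second pass removes the
tumor's own influence on the reference.

Four binary lesion masks — PET tumor, contrast-enhancing lesion, FLAIR
hyperintensity, resection cavity — are merged by voxelwise union into the
composite lesion mask.  Tumor location is the lobe with maximal volumetric
overlap with the PET mask (exact ties go deterministically to the lowest
template label and are flagged); the hemisphere comes from the sign of the
world-space x coordinate of the PET mask's center of gravity, with world +x
treated as right by default.

## BOLD conditioning

Three steps, in this order, each recorded in the output metadata:

1. **Nuisance regression** — each voxel series is replaced by its residual
   from a least-squares fit on an intercept, a linear trend (detrending is
   folded into the design; switchable) and the mean series of each nuisance
   mask (typically CSF and white matter).  Residuals are orthogonal to every
   regressor by construction.
2. **Temporal bandpass, 0.008–0.09 Hz** — a 4-pole Butterworth bandpass
   applied forward–backward (zero phase), so the magnitude response is the
   square of the single-pass response.  A zero-phase IIR filter was chosen
   over FFT masking for its robustness to edge effects; the per-voxel mean
   (0 Hz, below the passband) is removed before filtering to avoid DC edge
   transients.  Because the filter is linear, the package applies it as a
   `T × T` operator to the time-by-voxel matrix in one BLAS call, which is
   identical to per-voxel filtering to machine precision (tested).
3. **Gaussian smoothing, 5 mm FWHM** — separable convolution with
   `sigma = FWHM / (2 sqrt(2 log 2))` per axis in voxel units, reflective
   (half-sample symmetric) boundaries.  Reflection conserves the global sum,
   so no signal mass is created or destroyed at the brain edge.

Whether smoothing preceded or followed nuisance regression in the original
clinical processing chain is not documented; the order above is this
package's fixed, logged choice and is configurable.

## The FC estimator

For each of the seven canonical networks (visual, somatomotor, dorsal
attention, ventral attention, limbic, frontoparietal control, default mode):

1. **Crop** the binary network mask by the subject's composite lesion:
   `seed = network AND NOT lesion`.  Seeds smaller than 10 voxels (default)
   are unusable and yield a *missing* FC value — never zero, since a zero
   would masquerade as "no connectivity".
2. **Average** the BOLD series over the cropped seed (unweighted voxel
   mean) to obtain the network regressor.
3. **Regress** every in-brain voxel on the regressor (with intercept) and
   convert the fit to a z-scored connectivity map.
4. **Average** the z-map over the PET tumor mask: this is the
   tumor-to-network FC.

The mean of the available per-network FC values is the whole-brain FC.
Proximity is computed as the mean Euclidean distance, in world millimeters,
between the PET mask's center of gravity and the centroids of the network's
connected components ("nodes") of at least 5 voxels.

### The z-score

The z-score definition is the package's most consequential free choice,
since only "normalized to z-scores" is conventionally specified.  The
default is the correlation-equivalent Fisher z-statistic

\[ z = \operatorname{atanh}(r)\,\sqrt{T_{\mathrm{eff}} - 3}, \]

with `r` the Pearson correlation implied by the regression slope, clipped to
`|r| <= 1 - 1e-7` before `atanh`.  This is standard in seed-based FC, is
invariant to affine rescaling of either series, and produces values on the
single-digit scale typical of patient studies.  An alternative that
standardizes the regression slopes across in-brain voxels
(`variant = "spatial-z"`) is available behind a switch and excluded from the
default validation.

**Effective sample size.**  Bandpass filtering leaves only the fraction
`(f_high − f_low) / f_Nyquist` of the sampled spectrum, so neighboring
timepoints are strongly autocorrelated and the nominal `T` badly overstates
the information content.  The package uses

\[ T_{\mathrm{eff}} = T \cdot \frac{f_{high} - f_{low}}{1/(2\,\mathrm{TR})}
   = 2\,T\,\mathrm{TR}\,(f_{high} - f_{low}), \]

the brick-wall effective bandwidth.  For `T = 200`, `TR = 2 s` and the
default band this gives `T_eff ≈ 65.6`.  The choice is validated by a null
simulation (acceptance suite): with zero coupling, the empirical variance of
the z-scores is within a few percent of 1 (measured ≈ 1.02), i.e. the
Bartlett-type correction implied by the realized Butterworth response is
close enough to the brick-wall value that no filter-specific refinement is
needed.

## Cohort statistics

* **Group comparisons**: pooled-variance two-sided t-test for two groups,
  one-way ANOVA beyond.
* **Mixed repeated-measures ANOVA** across the 7 networks with an optional
  between-subject factor.  The F tables come from a multivariate linear
  model; the Greenhouse–Geisser epsilon is computed from the pooled
  within-group residual covariance `S` as
  `tr(CSC)^2 / ((k−1) tr((CSC)^2))` with `C` the double-centering projector,
  and multiplies the within-effect degrees of freedom.  For two within
  levels epsilon is exactly 1; degenerate (zero-variance) data are treated
  as spherical.
* **Kaplan–Meier / log-rank** with median survival defined as the first
  time the survivor function drops to 0.5 or below (undefined — `NA` — if
  never reached, not infinity).  Patients are grouped at the median or into
  quartile extremes (lower quartile / middle two / upper quartile, the
  21/40/21 pattern at n = 82); values tied with a cut go to the lower group,
  deterministically.
* **Cox proportional hazards** via the partial likelihood with Efron tie
  handling (Breslow available; clinical software often defaults to Breslow,
  and exact duplication invariance of estimates holds only under Breslow).
  Stepwise forward selection adds, at each step, the candidate with the
  smallest score-test p-value below `p_enter = 0.05` (the score test is
  evaluated at the current model's MLE with the new coefficient at zero, so
  the first step reduces to the classical log-rank test); backward exclusion
  drops the largest Wald p above `p_remove = 0.10`.  These thresholds are
  common defaults, fixed here because no values are conventionally agreed.
  An empty selection is a valid outcome and is reported with its trace.  No
  multiplicity correction is applied across the 7 univariate network tests
  by default.

## The synthetic cohort generator

The generator emulates exactly the features the estimator consumes:

* **Atlas**: seven disjoint parcels inside an ellipsoidal brain, each made
  of two spherical components so that proximity "nodes" are exercised; an
  8-lobe template (4 lobes × 2 hemispheres) partitions the brain.
* **BOLD**: each network has a latent time course — Gaussian white noise
  bandpassed to 0.008–0.09 Hz and scaled to unit variance, generated with a
  one-`T` padding margin so filter edge transients never reach the kept
  segment.  Network voxels carry their network's course plus white noise of
  unit standard deviation; tumor voxels carry the coupling-weighted sum
  `sum_k alpha_k s_k(t)` plus noise (tumor membership overrides parcel
  membership); remaining brain voxels are pure noise.  Tumor and normal
  tissue share the same noise model — how BOLD noise differs inside tumor
  tissue is not characterized in the literature this emulates, and the
  package makes that assumption explicit rather than inventing one.
* **PET**: uniform in-brain background activity, tumor voxels at
  `background × hotspot TBR` (default 2.0, near the reported cohort median
  of ~2.2), optional additive noise.  With zero noise the
  standardize-then-segment round trip recovers the planted tumor mask
  voxel-exactly at any threshold up to the hotspot TBR.
* **Structural masks**: contrast-enhancing mask inside the one-voxel tumor
  dilation, FLAIR mask as the two-voxel dilation (so FLAIR ⊇ CE, matching
  the typical volume ordering), optional displaced spherical cavity.
* **Tumor geometry**: an ellipsoid centered one parcel-radius inward from a
  target network's component, so it covers part — never all — of the parcel
  and extends beyond it, which makes seed cropping non-trivial.
* **Survival**: exponential proportional hazards
  `h(t|x) = h0 · exp(beta' x)` with the FC values (or, end to end, the
  planted couplings) among the covariates; independent exponential censoring
  calibrated to the target censored fraction; planted coefficients are
  returned for validation.  The default planted FC effect is −0.105 log-HR
  per z-score unit (HR 0.90), the magnitude scale at which such biomarkers
  are reported.  Simulated FC profiles share a subject-level factor
  (`sd 2.5`) on top of network-specific noise (`sd 2.0`), reproducing both
  the ~3 per-network SD and the strong inter-network correlation seen in
  patient cohorts; network means span 3.5–6.2 z-units.
* **Randomness**: a single integer seed fans out deterministically into
  per-component substreams, so identical seeds reproduce every volume and
  table bit-identically while modules can be re-run in isolation.

What the generator does **not** emulate: hemodynamic response shapes,
scanner artifacts, motion, physiological noise, registration error, and
spatially varying noise.  Green validation therefore demonstrates that the
estimator and statistics are correct *given* conditioned, co-registered
data; it does not certify robustness to acquisition artifacts.

## Numerical choices and edge cases

* Correlations are clipped at `1 − 1e-7` before `atanh`; zero-variance
  voxels get `z = 0` with a count flag; a zero-variance regressor is an
  error.
* Empty or undersized seeds propagate as missing values; the whole-brain
  mean uses the available networks.
* Exact overlap ties in lobe assignment go to the lowest label, flagged.
* The segmentation threshold comparison is `>=`, asserted by a voxel
  exactly at 1.6.
* Subject-level failures (e.g. grid mismatches) never abort a cohort run;
  they are recorded in the manifest with their reason.
* All distances use world millimeters through the shared affine, never
  voxel indices.

## Problem sizes used in validation

The validation suite runs entirely on synthetic data: the estimator oracle
on a 12³ grid with 120 timepoints; coupling recovery on 24³ grids over 100
seeds; null calibration on 16³ grids over 200 replicates; Cox recovery and
selection on cohorts of n = 400 over 100–200 replicates; and the end-to-end
pipeline on a full 80-subject cohort at 32³ and T = 200, run twice to
confirm byte-identical outputs.  These sizes were chosen so the whole suite
completes in minutes on a single CPU while keeping every Monte-Carlo
standard error well below the tolerance it guards.

## Known limitations

* The within-tumor noise model is identical to normal tissue (see above).
* The lesion-cropped single-regressor scheme is a deliberate simplification
  of full two-stage dual regression with group-ICA maps; dynamic FC and
  graph metrics are out of scope.
* `T_eff` uses the brick-wall bandwidth of the *configured* band; if a user
  narrows the band far enough that `T_eff <= 4`, the estimator refuses.
* With `p_enter = 0.05`, forward selection over 7 candidates retains *only*
  the true prognostic network in at most `0.95^6 ≈ 74%` of replicates —
  each null candidate still enters with ~5% probability after the true one.
  This is a property of stepwise selection at that threshold, not of the
  implementation.
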