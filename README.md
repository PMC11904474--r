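# gliomafc

Resting-state functional connectivity (FC) between an amino-acid-PET-defined
glioma region and the seven canonical resting-state networks, and its use as
a prognostic biomarker for overall survival.

Diffuse gliomas often remain functionally coupled to large-scale brain
networks, and stronger coupling of the metabolically active tumor region has
been associated with longer survival.  `gliomafc` implements the full
measurement chain for a patient with co-registered imaging:

* **Tumor definition** — PET activity is standardized to tumor-to-brain
  ratios (TBR) against the unaffected brain and segmented at TBR ≥ 1.6;
  PET, contrast-enhancing, FLAIR and resection-cavity masks merge into a
  composite lesion mask; tumor location is assigned by maximal lobe overlap.
* **BOLD conditioning** — CSF/WM nuisance regression with linear detrend,
  zero-phase Butterworth bandpass to 0.008–0.09 Hz, 5 mm FWHM Gaussian
  smoothing.
* **FC estimator** — each network mask is cropped by the composite lesion
  and its mean BOLD series regressed against every voxel; maps are
  normalized to Fisher z-scores, `z = atanh(r) · sqrt(T_eff − 3)`, where
  the effective sample size `T_eff = 2·T·TR·(f_high − f_low)` accounts for
  the bandpass; the mean z over the PET tumor mask is the tumor-to-network
  FC, the mean over networks the whole-brain FC, plus lesion-to-network
  proximities in mm.
* **Survival statistics** — Kaplan–Meier with log-rank tests on median or
  quartile-extreme FC groups, univariate and multivariate Cox
  proportional-hazards models with stepwise forward selection (score-test
  entry) confirmed by backward exclusion, and mixed repeated-measures ANOVA
  with Greenhouse–Geisser correction across the seven networks.
* **Synthetic cohorts** — a generator that plants bandlimited network time
  courses, tumor-to-network couplings, PET hotspots, lesion geometry and
  proportional-hazards survival with known coefficients, so every stage is
  validated against ground truth without patient data.

## Worked example

```r
library(gliomafc)

# one synthetic subject whose tumor couples to the dorsal attention network
p <- sim_imaging_params(seed = 3, coupling = c("dorsal-attention" = 2))
subj <- simulate_subject(p, subject_id = 1, hotspot_tbr = 2.0)
res  <- run_subject(subj, run_config())
round(res$profile[, 2:9], 2)
#>   fc_vis fc_som fc_dan fc_van fc_lim fc_fpc fc_dmn fc_mean
#> 1    0.5   0.16  20.55   0.63  -1.48  -0.22  -1.45    2.67
res$profile$vol_pet_ml   # 0.88 (mL, PET-avid tumor at TBR >= 1.6)
res$profile$tbr_mean     # 2.0  (noiseless hotspot at TBR 2.0)
```

The coupled network dominates the FC profile (z ≈ 20.6 at coupling 2 with
unit noise) while uncoupled networks stay at null scale (|z| ≈ 1), and the
noiseless PET round trip returns the planted TBR exactly.

A cohort run takes a list of subjects plus a clinical table and produces the
profile table, univariate and stepwise Cox models, Kaplan–Meier groups and
the repeated-measures ANOVA in one call:

```r
made <- synth_make(n_subjects = 20, imaging = sim_imaging_params(seed = 1),
                   lazy = TRUE)
res <- run_cohort(made$subjects, made$clinical, run_config(seed = 1))
res$stepwise_forward$selected   # networks retained by forward selection
res$km$medians                  # median OS per FC quartile group
write_cohort_results(res, "results/")
```

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/gliomafc.R synth  --out study --n 20 --seed 1
Rscript inst/cli/gliomafc.R cohort --in study --out results --seed 1
```

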