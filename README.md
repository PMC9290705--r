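# pbdlmrq

Multiparametric quantitative MRI analysis of the partial bile duct
ligation (PBDL) mouse model of cholestatic liver fibrosis.

PBDL ligates the bile duct of selected liver lobes, so the same animal
carries fibrotic (ligated) and healthy (non-ligated) tissue; quantitative
MRI parameters — native T1, the post-contrast shortening ΔT1, T2, T2\*,
the apparent diffusion coefficient (ADC) with its histogram shape, and the
intravoxel-incoherent-motion (IVIM) parameters *f*, *D*, *D*\* — can stage
the fibrosis (Metavir F0–F4) and inflammation (A0–A3) non-invasively.
`pbdlmrq` implements that study end to end on synthetic data: it simulates
a 54-mouse cohort (12 PBDL mice at each of 2, 4, 6, 8 weeks post-surgery,
each contributing two lobes, plus 6 sham mice) with known tissue
parameters, fits every voxel-wise parameter map under Rician noise, and
runs the group-comparison, correlation, feature-selection and ROC
statistics that evaluate the parameters as fibrosis biomarkers. It is
aimed at preclinical imaging researchers who want a tested, reproducible
reference implementation of this analysis chain, or a calibrated phantom
to validate their own.

## Models

Voxel-wise fits use closed-form steady-state signal equations:

* **T1 (variable flip angle):** S(θ) = M₀ sinθ (1−E₁)/(1−E₁ cosθ) with
  E₁ = exp(−TR/T1), at flip angles 5°/26°, TR 15 msec; linearized solve
  (slope of S/sinθ vs S/tanθ) refined by Levenberg–Marquardt.
  ΔT1 = T1_native − T1_post, voxel-wise.
* **T2, T2\* (multi-echo):** S(TE) = M₀ exp(−TE/T), log-linear least
  squares with the first echo discarded.
* **ADC (two-point):** ADC = ln(S₀/S₈₀₀)/800 from b = 0 and 800 s/mm².
* **IVIM (nine b-values, 0–1000 s/mm²):**
  S_b/S₀ = (1−f) exp(−bD) + f exp(−bD\*), segmented initialization
  (log-linear over b ≥ 200 s/mm²) followed by a full bounded
  Levenberg–Marquardt fit.

Cohort statistics: Shapiro–Wilk-gated ANOVA/Kruskal–Wallis with
Bonferroni-corrected pairwise tests, Spearman rank correlation against
histology stages, forward selection (|r| > 0.60, p < 0.05), and ROC with
pair-counting AUC, a logistic "combined" score, and Youden-index cutoffs.

## Worked example

```r
library(pbdlmrq)

# simulate one ligated-lobe acquisition at SNR 50 and fit every map
truth <- tissue_params(t1_native = 966.31, delta_t1 = 468.083, t2 = 35.922,
                       t2star = 12.729, adc = 1.179, d = 1.087)
vols <- simulate_lobe_volumes(truth, acquisition_protocol(),
                              grid_shape = c(32, 32, 2), snr = 50, seed = 1)
maps <- fit_lobe_maps(vols)
summarize_roi(maps$t1_native, vols$roi_mask, vols$exclusion_mask)

# cohort-level ROC for delta-T1 and for the combined logistic score
cohort <- sample_cohort(cohort_design(seed = 2026))
roc_analysis(cohort, "delta_t1")
roc_analysis(cohort, c("delta_t1", "t2", "adc"))
```

This prints (ROI means over 1472 voxels, then the 102-lobe cohort ROC):

```
t1_native  ROI mean  967.118 (truth  966.310, n = 1472 voxels)
delta_t1   ROI mean  467.426 (truth  468.083, n = 1472 voxels)
t2         ROI mean   36.348 (truth   35.922, n = 1472 voxels)
adc        ROI mean    1.178 (truth    1.179, n = 1472 voxels)
delta-T1 AUC 0.877 (cutoff 507.0 msec, sens 0.771, spec 0.833)
combined AUC 0.998
```

The fitted ROI means sit within a fraction of a percent of the imprinted
tissue values, and ΔT1 alone separates fibrotic from non-fibrotic lobes
with AUC ≈ 0.88 on a single simulated cohort; combining ΔT1, T2 and ADC
through a logistic score raises discrimination to near-perfect.

## Analysis workflow

The `analysis/` directory holds the numbered study drivers, each a thin
script over the package functions, writing tables under `results/`:

1. `01_simulate_cohort.R` — sample the default cohort, write ground truth,
   design YAML and an example animal's NIfTI volumes.
2. `02_fit_parameter_maps.R` — map-level round-trip accuracy, noiseless
   and at SNR 50.
3. `03_run_pipeline.R` — the full simulate → fit → summarize → statistics
   pipeline (`run_pipeline()`), producing the observation table,
   comparison and correlation tables, and ROC results.
4. `04_roc_replicates.R` — the distribution of the ΔT1 and combined AUC
   over 200 replicate cohorts.

A methods vignette (`vignettes/pbdl-multiparametric-mri.Rmd`) documents
the models, the generator calibration, the noise model and the design
decisions.

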