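---
title: "Multiparametric quantitative MRI of the PBDL mouse model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric quantitative MRI of the PBDL mouse model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbdlmrq)
```

## The problem this package addresses

Partial bile duct ligation (PBDL) in the mouse produces cholestatic liver
fibrosis in the ligated lobes while sparing the non-ligated lobes, giving a
within-animal comparison of fibrotic and healthy tissue. Multiparametric
quantitative MRI — T1, ΔT1, T2, T2\*, ADC and IVIM parameters — can stage
this process non-invasively against Metavir fibrosis (F0–F4) and
necro-inflammatory activity (A0–A3) scores. Because the underlying animal
images are not public, this package rebuilds the entire analysis as a
simulation-to-statistics pipeline: a synthetic cohort with known tissue
parameters stands in for the scanned animals, and every downstream stage
(voxel-wise fitting, ROI summarization, group statistics, ROC) is the same
code a real study would run on NIfTI volumes.

## Signal models

All fits use closed-form steady-state signal equations; there is no
Bloch-equation simulation.

**Variable-flip-angle T1.** Spoiled-gradient-echo steady state,

$$S(\theta) = M_0 \sin\theta \,\frac{1 - E_1}{1 - E_1\cos\theta},
  \qquad E_1 = e^{-TR/T_1},$$

acquired at flip angles 5° and 26° with TR 15 msec. The fit linearizes
($S/\sin\theta$ regressed on $S/\tan\theta$, slope $E_1$) and then refines
by Levenberg–Marquardt. With exactly two angles the linearized solution
interpolates the data, so it is already the Levenberg–Marquardt fixed
point; the refinement step only iterates for over-determined protocols.
The post-contrast map uses the same model at
$T_{1,\mathrm{post}} = T_{1,\mathrm{native}} - \Delta T_1$, and the ΔT1 map
is the voxel-wise difference of the two fits on the intersection of their
valid masks (negative voxels are retained and counted, not clipped).

**T2 and T2\*.** Mono-exponential decay $S(TE) = M_0 e^{-TE/T}$, fitted by
ordinary least squares of $\ln S$ on TE, the way clinical workstations
produce these maps. The first echo is discarded by default; the source
protocol states this rule for the T2 calculation, and the package applies
it to the T2\* train as well (one workstation rule generated both maps), with
`discard_first = FALSE` available. No weights are used — the fit is plain
OLS in the log domain. Echoes with nonpositive signal are dropped per
voxel; a voxel needs two usable echoes and a negative slope, and fitted
times outside (0.1, 10000] msec are marked invalid. These validity bounds
are this package's declared choices, not reverse-engineered workstation
behaviour.

**Diffusion.** The two-point ADC map inverts
$S_b/S_0 = e^{-b\,\mathrm{ADC}}$ at $b = 0$ and $800\ \mathrm{s/mm^2}$.
The IVIM fit uses the bi-exponential model

$$S_b/S_0 = (1 - f)\,e^{-bD} + f\,e^{-bD^*}$$

over all nine b-values (0–1000 s/mm²), with the segmented initialization
that is standard for liver IVIM: a log-linear fit over $b \ge 200$ gives
$D$ and an intercept, $f$ starts at one minus the intercept ratio, $D^*$
comes from a one-dimensional search, and a full Levenberg–Marquardt fit of
$(S_0, f, D, D^*)$ follows, bounded by $f \in [0,1]$ and
$D, D^* \in (0, 500]$ (in $10^{-3}\ \mathrm{mm^2/s}$). The fitted, not
measured, $b=0$ intercept serves as $S_0$ in the final model. The split
point 200 s/mm² is configurable. A voxel whose compartments cross is
relabelled and flagged; $f$ pinned at a bound is flagged because $D^*$ is
then unidentifiable.

**Histogram summaries.** ADC histogram mean, skewness and excess kurtosis
use Fisher's bias-uncorrected moment ratios; skewness needs three voxels,
kurtosis four, and a constant ROI leaves both undefined while the mean is
still reported. A bias-corrected variant is available behind a flag.

## The synthetic cohort

The generator is calibrated to the published group summaries: for each of
native T1, ΔT1, T2, T2\*, ADC and D it stores the (mean, sd) of the
ligated and non-ligated lobes at 2, 4, 6 and 8 weeks and of the sham
livers, and draws each lobe's parameters independently from the
corresponding normal cell, truncated to physical validity (positive
relaxation times, $f \in [0,1]$, $D^* > D$, post-contrast T1 > 0). Design
choices worth knowing:

* **Sham animals are scanned once.** The published sham summaries repeat
  identically across timepoints, so sham lobes carry no timepoint and
  re-enter every timepoint comparison.
* **ΔT1 is sampled independently of native T1** within a lobe; the source
  tables do not constrain their covariance. This is the least-assumption
  default; the post-contrast T1 is derived as the difference and kept
  positive by truncation.
* **f, D\* and M0 are not tabulated** in the source; the defaults
  (f = 0.20 ± 0.05, D\* = 50 ± 10 × 10⁻³ mm²/s, M0 = 1000) are typical
  rodent-liver values, identical across groups, and therefore carry no
  group signal. They are excluded from any quantitative claim.
* **DWI generation defaults to mono-exponential** with the tabulated ADC as
  ground truth, so ADC round-trips are exact; an `"ivim"` mode generates
  from $(f, D, D^*)$ for IVIM recovery studies. The tabulated ADC and D
  come from different fits in the source and need not be consistent under
  one model, which is why the generator does not try to satisfy both at
  once.
* **Histology trajectory.** Ligated lobes progress F1, F2, F2, F3 at 2, 4,
  6, 8 weeks, with activity A2, A3, A2, A3; non-ligated and sham lobes stay
  (F0, A0). A jittered mode perturbs each stage by ±1 with configurable
  probability, pinning the 8-week endpoint at (F3, A3).

### Noise model

Voxel noise is Rician — Gaussian noise of scale σ on two quadrature
channels followed by the magnitude operation — applied to every series.
The noise level is specified as a per-series SNR: σ is the series' peak
noiseless signal divided by the SNR (default 50), which matches how SNR is
quoted on the brightest image of an acquisition. This matters because the
two-angle spoiled-gradient-echo signals are only ~6–7 % of $M_0$ at TR 15
msec: a σ tied to the proton-density scale would leave the T1 series at an
effective SNR near 3, where variable-flip-angle T1 is not recoverable to
within a few percent. An absolute σ can be given instead. The tabulated
group SDs are treated as between-animal variability, never as voxel noise.

Two consequences of Rician noise are deliberately left visible rather than
corrected: late-echo decay signals acquire a positive bias floor, so T2
and especially T2\* (whose retained echoes decay to SNR ≲ 2 by the last TE)
are biased upward at low SNR — the test suite asserts the direction of
this bias, not a magnitude — and noise can push $S_b$ above $S_0$,
producing negative ADC voxels, which are excluded from ROI summaries and
counted in the diagnostics.

### Masks and leakage detection

Each simulated lobe carries a boolean ROI mask and a disjoint exclusion
mask emulating vessels/bile ducts. Exclusion voxels are simulated from a
deliberately out-of-distribution parameter set (longer relaxation, faster
diffusion, brighter M0) so that a summary that forgets to exclude them is
visibly wrong — a plain brightness change would be invisible to the
scale-invariant T1/T2/ADC fits. Voxel grids are index-based; there are no
world coordinates.

## Statistical workflow

ROI summaries (mean over retained voxels) of each fitted map form one
observation row per lobe. On these:

* **Group comparisons** per parameter and timepoint: Shapiro–Wilk at
  α = 0.05 on each group's centered values gates between one-way ANOVA
  (with pairwise Welch t tests) and Kruskal–Wallis (with pairwise
  rank-sum tests); pairwise p-values are Bonferroni-corrected over the
  three pairwise comparisons, which is the declared correction family.
  Groups too small for Shapiro–Wilk (n < 3) contribute no evidence against
  normality.
* **Spearman correlations** of each parameter with fibrosis and activity
  stage use average ranks (ordinal stages are heavily tied) and the
  two-sided t approximation for p.
* **Feature selection** keeps parameters with $|r| > 0.60$ and $p < 0.05$
  against fibrosis. Native T1 passes this rule in the source data
  (r = 0.667) yet the published combination uses only ΔT1, T2 and ADC;
  the package therefore drops native T1 by default whenever ΔT1 is also
  selected — the two largely duplicate contrast-uptake information — and
  keeps it when `exclude_if_selected = NULL`.
* **ROC.** Single-parameter scores are sign-oriented so higher means more
  fibrotic (AUC ≥ 0.5 convention); the combined score is the linear
  predictor of a binomial logistic regression on the selected parameters,
  the standard "combined ROC" workflow, with coefficients reported. AUC is
  the pair-counting (Mann–Whitney) estimate with half credit for ties; the
  operating point maximizes Youden's J over midpoints between adjacent
  sorted scores, ties (including floating-point ties) broken toward the
  lowest cutoff. The positive class defaults to fibrosis stage ≥ 1, and
  all timepoints are pooled into one ROC cohort with sham counted once;
  both choices are configurable because the source does not state them.
  Confidence intervals (DeLong/bootstrap) are out of scope, as are mixed
  models for the paired-lobe design.

## Problem sizes and reproducibility

The package's own validation uses: noiseless round-trips on small grids
(exactness to 10⁻⁶ relative, 10⁻⁴ for IVIM); 10,000-voxel ROIs at SNR 50
for the noisy map-level round-trips; 200 replicate cohorts for the
ROC summaries; and 30 replicate cohorts for the correlation-ordering
checks. Every random draw flows from one integer seed per run
(`cohort_design(seed = )`, or `--seed` in `scripts/acceptance.R`); the
pipeline derives per-stage substreams from it so that, for example,
changing a statistics option cannot perturb the simulated cohort.
Identical configuration and seed give byte-identical output files, and
each output CSV records the configuration hash in its header. Tables are
written with six significant digits; a full-precision JSON sidecar
accompanies the observation table.

## What passing tests do and do not show

The synthetic cohort reproduces the *group structure* of the study —
between-animal means and SDs, the histology trajectory, the pooled-cohort
discrimination — and the fits run on honestly noisy voxel data. It does
not emulate partial-volume effects at lobe boundaries, respiratory motion,
B1 inhomogeneity (no B1 correction is applied), registration error between
sequences, or any spatial correlation of tissue properties: every ROI
voxel of a lobe shares one ground-truth parameter set. Passing round-trip
tests therefore validate the estimators and the statistical machinery, not
the biological claim; correlations measured on fitted summaries are mildly
attenuated relative to ground truth (noise in the summaries), which is
visible in cohort-level results — for instance, the ADC–fibrosis
correlation sits close to the 0.60 selection threshold, so whether ADC
enters the data-driven combination varies across simulated cohorts. The
replicate-averaged ROC targets instead use the fixed published
combination (ΔT1, T2, ADC), so they are unaffected by that variability.

## Known limitations

* Two flip angles make the VFA fit exactly determined per voxel: residuals
  carry no lack-of-fit information, and B1 errors would alias directly
  into T1.
* The T2\* protocol's late echoes sit near the noise floor at SNR 50, so
  T2\* summaries inherit a visible upward Rician bias; the package reports
  it rather than correcting it.
* IVIM's $D^*$ is weakly identified at f ≈ 0 (mono-exponential tissue);
  such voxels are flagged rather than silently reported.
* The generator's independence assumptions (across parameters within a
  lobe, and between native T1 and ΔT1) are defaults, not facts about the
  tissue; a correlation-aware generator would need covariance information
  the source does not provide.
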