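---
title: "Quantitative DSC perfusion analysis: models, choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative DSC perfusion analysis: models, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package computes

Dynamic susceptibility contrast (DSC) MRI tracks the first pass of a
gadolinium bolus through the brain with a rapid T2\*-weighted sequence.
`dscquant` turns a 4D bolus-tracking series into calibrated cerebral blood
flow (CBF, ml/100 g/min) and blood volume (CBV, ml/100 g) maps, extracts
VOI-level relative perfusion ratios for subcortical structures, and compares
patient and control groups with nonparametric tests. A digital perfusion
phantom with known ground truth validates every stage end to end.

## Signal model and concentration conversion

The susceptibility effect of the tracer is modelled by the standard
single-exponential relation

$$S(t) = S_0 \, e^{-TE \cdot k \cdot C(t)},$$

with the proportionality constant fixed at $k = 1$, so concentrations are in
arbitrary units. This is deliberate: every reported quantity is either a
ratio (rCBF, rCBV) or is calibrated against the white-matter internal
standard, and $k$ cancels in both. $S_0$ is the mean signal over the
pre-bolus baseline window — by default timepoints 1–8, or all points before
the global-mean signal first drops 5% below its running baseline, whichever
is shorter. Non-positive signal samples (possible under noise) map to
$C = 0$ and are counted rather than propagated as NaN. Negative
concentrations are clipped to zero for descriptor and integral computations
but preserved in the stored volume.

## Arterial input function

Arterial voxels are recognized by three curve descriptors: high peak
concentration (Cmax), short time-to-peak (TTP) and short first-moment
transit time (fMTT). Each candidate voxel receives the composite score
$\mathrm{rank}(-C_{max}) + \mathrm{rank}(TTP) + \mathrm{rank}(fMTT)$; the
equal-weight rank sum is scale-free in all three descriptors, which is why
it was chosen over any weighted combination of raw values. The best 20
voxels (configurable) are averaged, smoothed with a 3-point moving average,
and truncated — zeroed after the first local minimum following the global
peak — to remove the recirculation (second-pass) bump. If no post-peak local
minimum exists the curve is kept whole. A gamma-variate fit would be the
classical alternative truncation rule; it is not the default because fits
on ~60-point curves are unstable at realistic noise. The search region is
the parenchyma mask (which still contains vessels — that is where arteries
are), and selection is volume-wise, not per-slice.

## Deconvolution and maps

The tissue curve obeys the indicator-dilution convolution
$C_t(t) = \tfrac{CBF}{6000}\,(C_a \ast R)(t)$ with residue function
$R$ ($R(0)=1$, nonincreasing; 6000 converts ml/100 g/min to 1/s per gram).
CBF is estimated by truncated singular value deconvolution: the
lower-triangular Toeplitz matrix $A_{ij} = \Delta t\, C_a(t_{i-j})$ is
pseudo-inverted with singular values below $0.2\,\sigma_{max}$ zeroed —
the classical standard-SVD threshold, chosen for reproducibility; oscillation-index
or block-circulant variants are out of scope. CBF is read off as the
*maximum* of the flow-scaled residue rather than its value at $t = 0$, to
tolerate bolus delay. CBV is the trapezoidal integral ratio
$\int C_t / \int C_a$. Negative outputs are clipped to zero in the maps.

Truncated SVD at this threshold systematically underestimates high flows
(short MTTs) — a well-known property of the method, reproduced faithfully
here. Because white matter shares the bias direction, the internal-standard
calibration cancels most of it: on the noise-free phantom the calibrated
regional CBF error stays within 15% for all gray-matter structures, and
CBV, which needs no deconvolution, calibrates to under 1% error (both
recomputed by `scripts/acceptance.R`).

## Masks

The parenchyma mask is a two-stage intensity segmentation of the anatomical
volume: a background/head split by Otsu's criterion computed on intensity
*ranks* (so the split is invariant under any strictly monotone intensity
rescaling), then a three-class quantile split of head voxels keeping the
upper two classes, then the largest 6-connected component. This replaces a
full EM tissue segmentation, which would be unnecessary for the phantom's
well-separated intensity classes and is out of scope for real data.

The vessel mask flags voxels whose Cmax strictly exceeds 3.0 times the
median Cmax over parenchyma voxels (the parenchyma mask is applied before
the histogram is taken; the "histogram" is treated as the empirical
distribution — no binning, so the rule is bin-width independent). The
comparison is strict (>), and the factor is per-subject and configurable.
The analysis inclusion mask is parenchyma AND NOT vessel.

## Calibration and VOI ratios

Normal white matter serves as an internal standard: maps are rescaled so
the white-matter VOI means equal 22 ml/100 g/min and 2.7 ml/100 g exactly.
Per structure and side, the mean CBF/CBV over (VOI ∩ inclusion mask) is
reported together with the dimensionless ratios rCBF and rCBV against the
white-matter reference mean on the same masked basis. Ratios are identical
whether computed before or after calibration. VOIs that are empty after
masking yield missing values with a warning, never silent zeros. The label
map is the single source of laterality truth; no radiological/neurological
flip logic is applied.

## Statistics

Group contrasts (patients vs controls, per structure × side × metric) use
the Mann-Whitney U test; within-patient laterality contrasts (right vs
left, per structure × metric) use the Wilcoxon signed-rank test. Both are
implemented with explicit modes: exact p-values by full enumeration
($\binom{n+m}{n}$ labelings, or $2^k$ sign patterns) when the total sample
size is at most 12 in auto mode, otherwise the normal approximation with
tie-corrected variance and continuity correction. Ties contribute ½ to U;
the statistic is reported in min-form. A test on all-zero paired
differences is reported as undefined, not as $p = 1$. All tests are
two-sided at α = 0.05, and no multiplicity correction is applied — the
result table carries the test count so users can apply their own. With five
patients the exact two-sided Wilcoxon floor is $2/2^5 = 0.0625$, so
laterality contrasts in exact mode can never fall below 0.05; the
asymptotic mode is exposed for users who want the SPSS-like behavior.

## The digital phantom

The phantom is an ellipsoidal "head" of white matter containing six
bilateral subcortical boxes (amygdala, hippocampus, thalamus, putamen,
globus pallidus, caudate) and a small vertical arterial column, on a
48×48×12 matrix with 60 timepoints at TR 1.5 s and TE 46 ms. The arterial
input is a gamma-variate ($t_0 = 10$ s, $\alpha = 3$, $\beta = 1.5$ s — the
canonical simulation shape) plus a delayed, dispersed recirculation bump at
30% of first-pass amplitude, so that truncation logic has a second pass to
remove. Tissue curves are the convolution of this input with exponential
residues; they are synthesized on a fine internal grid (50 ms) and sampled
at TR, because a rectangle-rule convolution on the TR grid would inflate
CBV by an MTT-dependent 9–19% — a discretization artifact, not physiology.
Gaussian noise is added to the *signal* (not the concentration), matching
magnitude MR acquisition at moderate SNR.

Ground-truth values: white matter carries the internal-standard presets
(22 / 2.7); the subcortical structures carry deep-gray-matter perfusion
values from the PET literature (CBF 42–58 ml/100 g/min, CBV 3.2–4.1
ml/100 g), which run lower than cortical gray matter; MTT follows from the
central volume theorem $MTT = 60 \cdot CBV / CBF$ (4.2–4.6 s). Arterial
voxels carry the undispersed input directly, giving them the highest Cmax
and earliest TTP by construction. The bolus amplitude is set so that at
TE 46 ms the arterial signal drops by ~84% and tissue by a few percent —
the regime of a real gradient-echo acquisition, where arterial voxels are
near saturation while tissue stays in the linear range.

Cohorts follow the matched design of the motivating study population: 5
patients, each with 3 matched controls (20 subjects). Patients have CBF and
CBV multiplied by `effect_fraction` (default 0.8) in the effect regions
(default: both hippocampi); MTT is untouched by this scaling, preserving
central-volume consistency. Per-subject seeds derive deterministically from
the design seed, so a cohort is bit-reproducible. Bolus arrival time and
scan delay are not constrained by any published value and are free
parameters of the generator.

### What the phantom does *not* emulate

No k-space physics, motion, partial-volume mixing, susceptibility
artifacts, leakage (no K2 correction exists downstream either), or
between-subject anatomical variability. Subjects differ only in noise
realization (and truth scaling for patients). Passing tests therefore
demonstrate correctness of the *computational* pipeline under known ground
truth — not robustness to the full messiness of clinical data.

## Problem sizes used in validation

Single-study checks (parameter recovery, calibration, AIF selection) run on
the standard 48×48×12×60 phantom. The Monte-Carlo checks (type-I error over
500 null cohorts; power over 200 cohorts per effect level at
`effect_fraction` ∈ {1.0, 0.9, 0.8, 0.7}) run the full per-subject pipeline
on a compact 24×24×8×40 phantom with the AIF average scaled to its arterial
column (6 voxels), a size chosen so each 20-subject cohort quantifies in
under a second while retaining all six bilateral structures, white matter
and an arterial column. At this scale the null rejection rate of the
hippocampal group contrast sits near the nominal 0.05 and detection power
rises steeply as the effect fraction falls — the quantities recomputed by
`scripts/acceptance.R`.

## Known limitations

* sSVD flow underestimation is inherited by design; absolute CBF accuracy
  relies on the white-matter calibration transferring the bias ratio, which
  holds when regional MTTs are in the physiological range but degrades for
  extreme MTT contrasts.
* The vessel rule assumes a unimodal parenchymal Cmax distribution; a
  degenerate (all-zero) distribution is rejected with an error.
* Exact tests enumerate; they are intended for the small cohort sizes of
  this design (the auto mode switches to the tie-corrected normal
  approximation beyond a total of 12 observations).
* The per-voxel CBF noise floor biases VOI means upward under heavy noise —
  visible in the phantom as compression of rCBF toward 1 at low SNR. Group
  comparisons remain valid (the bias is common to both groups), but
  absolute ratios at low SNR should be read with care.
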