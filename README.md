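# dscquant

Quantitative analysis of dynamic susceptibility contrast (DSC) perfusion
MRI, aimed at group studies of subtle perfusion changes — the setting where
visual inspection of perfusion-weighted images finds nothing and only
VOI-level statistics against matched controls can reveal regional
hypoperfusion (e.g. in transient global amnesia, migraine aura, or
diaschisis).

The pipeline takes a 4D bolus-tracking series, an aligned anatomical
volume and a subcortical label map, and produces calibrated CBF/CBV maps,
relative perfusion ratios per structure and hemisphere, and nonparametric
group comparisons:

1. **Concentration**: $C(t) = -\ln(S(t)/S_0)/(TE \cdot k)$ with $S_0$ from
   an auto-detected pre-bolus baseline.
2. **AIF**: voxels ranked by rank-sum of (high $C_{max}$, short $TTP$,
   short $fMTT$); the best 20 averaged, smoothed, and truncated after the
   first pass.
3. **CBF**: truncated-SVD deconvolution of the Toeplitz convolution system
   $C_t = \tfrac{CBF}{6000} A\,R$, singular values below
   $0.2\,\sigma_{max}$ zeroed, CBF read at the residue peak.
   **CBV**: $\int C_t / \int C_a$ by trapezoidal quadrature.
4. **Masks**: parenchyma from the anatomical volume (rank-Otsu +
   quantile split + largest component); vessels where
   $C_{max} > 3.0 \times$ median parenchymal $C_{max}$; analysis mask =
   parenchyma AND NOT vessel.
5. **Calibration**: white matter as internal standard, preset to
   22 ml/100 g/min and 2.7 ml/100 g.
6. **Statistics**: exact or tie-corrected-asymptotic Mann-Whitney U
   (patients vs controls) and Wilcoxon signed-rank (left vs right),
   two-sided, α = 0.05, medians with IQR, no multiplicity correction.

A digital perfusion phantom (ellipsoidal white-matter "head", six bilateral
subcortical structures, an arterial column, gamma-variate bolus with
recirculation, known regional CBF/CBV/MTT) and a matched patient/control
cohort simulator provide ground truth for end-to-end validation.

## Worked example

```r
library(dscquant)

## one noise-free phantom subject, quantified end to end
acq <- acquisition_params(n_timepoints = 40L, matrix_shape = c(24L, 24L, 8L))
study <- generate_study(acq, noise_sigma = 0)
res <- quantify_study(study, pipeline_config(n_aif = 6L))
head(res$voi[, c("structure", "side", "n_voxels", "cbf_mean", "cbv_mean",
                 "rcbf", "rcbv")], 4)
#>     structure  side n_voxels cbf_mean cbv_mean  rcbf rcbv
#> 1    amygdala right        9    40.18    3.645 1.826 1.35
#> 2    amygdala  left        9    40.18    3.645 1.826 1.35
#> 3 hippocampus right        9    41.74    3.752 1.897 1.39
#> 4 hippocampus  left        9    41.74    3.752 1.897 1.39
```

`cbf_mean` is in ml/100 g/min after white-matter calibration (truth for the
amygdala is 46: truncated-SVD flow underestimation leaves it ~13% low,
within the method's expected tolerance); `rcbf` is the dimensionless ratio
to white matter. With a simulated cohort (5 patients, 15 matched controls,
20% bilateral hippocampal CBF/CBV reduction in patients):

```r
out <- run_cohort_analysis(cohort_design(seed = 1), acq,
                           pipeline_config(n_aif = 6L))
format_comparison_table(out$results, "rcbf")
#> | Region | Patients rcbf | Controls rcbf | p |
#> |---|---|---|---|
#> | R amygdala | 1.22 (1.17-1.24) | 1.23 (1.18-1.29) | 0.541 |
#> | L amygdala | 1.28 (1.21-1.30) | 1.27 (1.14-1.31) | 0.727 |
#> | R hippocampus | 1.06 (1.03-1.08) | 1.24 (1.16-1.31) | 0.002 |
#> | L hippocampus | 1.03 (1.01-1.06) | 1.23 (1.18-1.32) | 0.018 |
```

The induced hippocampal hypoperfusion is detected bilaterally while the
unaffected regions stay null — the group-comparison workflow in miniature.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/dscq.R simulate --out cohort/ --seed 1
Rscript inst/cli/dscq.R quantify --dir cohort/
Rscript inst/cli/dscq.R compare  --dir cohort/
```

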