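# qsmsci

Quantitative MRI of silent cerebral infarcts (SCI): susceptibility
(QSM) and R2\* mapping, threshold-based lesion segmentation, and paired
lesion-vs-control statistics — as one tested R package.

SCI are small FLAIR-hyperintense white-matter lesions found in
neurologically asymptomatic people, most commonly in sickle cell
anemia, and their tissue composition is an open question. Two
quantitative contrasts address it: magnetic susceptibility χ (ppm;
myelin diamagnetic, iron paramagnetic) and the effective transverse
relaxation rate R2\* (s⁻¹; rises with total susceptibility-source
load). The analysis compares each lesion against a mirrored
contralateral region of normal-appearing white matter (NAWM): a lesion
that is less diamagnetic with lower R2\* than its NAWM pair points to
myelin loss or increased water content.

The package is aimed at quantitative-MRI researchers who want the full
chain — from raw multi-echo complex data to lesion statistics — in
reproducible, testable form, together with a digital phantom that
provides ground truth for every stage.

## What it computes

- **Phantom + simulation** — nested-ellipsoid brain with ground-truth
  χ / R2\* / M0, ellipsoidal white-matter lesions, ME-GRE signal
  (7 echoes, TE₁ = 3 ms, ΔTE = 4 ms, 3 T, 1.15 mm isotropic), FLAIR
  (0.65 × 0.65 × 1 mm) and T1w (1 mm) contrasts with controlled lesion
  behaviour (`build_phantom`, `simulate_megre`, `simulate_structural`,
  `write_dataset`).
- **Field mapping** — phase-difference coil combination, per-voxel
  complex fit of `M0·exp(−R2*·TE)·exp(i(φ0 + 2πf·TE))`, Laplacian
  phase unwrapping with exact congruence restoration, B0 realignment
  (`combine_coils`, `fit_field_nonlinear`, `unwrap_field`,
  `align_to_b0`).
- **QSM** — dipole kernel `D(k) = 1/3 − k∥²/|k|²`, background removal
  by projection onto dipole fields, Tikhonov-regularized dipole
  inversion `argmin ‖W(Dχ − f)‖² + α‖χ‖²` with default α = 0.013, and
  L-curve weight selection (`remove_background_pdf`, `invert_tikhonov`,
  `lcurve_select_alpha`).
- **R2\*** — voxelwise log-linear fit: R2\* = −slope of ln S vs TE
  (`fit_r2star_loglinear`).
- **Segmentation** — two lesion definitions (FLAIR: intensity ≥ 1.02 ×
  mean cortical FLAIR; stringent FLAIR+T1w: additionally ≤ 1.02 × mean
  cortical T1w), 3 mm minimum greatest dimension, exclusion of lesions
  reduced to ≤ 2 voxels after interpolation into QSM space,
  contralateral NAWM mirroring, periventricular / juxtacortical / deep
  classification by distance-transform percentiles, lobe assignment
  (`apply_flair_threshold`, `apply_t1w_threshold`, `size_gate`,
  `mirror_nawm`, `classify_wm_depth`, `assign_lobe`).
- **Statistics** — paired t, Bland–Altman limits of agreement, log-age
  correction, sequential ANOVA (ln age, group, lobe, ln volume),
  Student's t / Tukey HSD group comparisons, Pearson correlations
  (`paired_delta`, `bland_altman`, `age_correct`, `anova_effects`,
  `group_compare`, `cognition_correlate`, `correlate_paired`).
- **Pipeline** — `run_all(run_config())` runs
  simulate → reconstruct → segment → pair → summarize deterministically
  from one seed. A thin CLI lives at `inst/cli/qsmsci.R`.

See `vignettes/qsmsci-methods.Rmd` for the models, conventions and
design decisions.

## Worked example

```r
library(qsmsci)

cfg <- run_config()          # 64^3 phantom, 10 lesions, alpha = 0.013
res <- run_all(cfg)

st <- res$stats$FLAIR
sprintf("delta chi = %.5f ppm (t = %.2f, p = %.3g)",
        st$chi$delta, st$chi$t, st$chi$p)
#> "delta chi = 0.00696 ppm (t = 13.62, p = 8.11e-07)"
sprintf("delta R2* = %.3f 1/s", st$r2star$delta)
#> "delta R2* = -2.500 1/s"
head(res$records[, c("lesion_id", "definition", "lobe", "volume_mm3",
                     "mean_chi_sci", "mean_chi_nawm")], 3)
#>   lesion_id definition    lobe volume_mm3 mean_chi_sci mean_chi_nawm
#> 1         1      FLAIR frontal     106.46     0.005367     -0.001452
#> 2         2      FLAIR frontal      97.34     0.004195     -0.001722
#> 3         2  FLAIR+T1w frontal      38.02     0.004251     -0.007076
res$excluded[1:2, ]
#>   lesion_id definition                              reason
#> 1         1  FLAIR+T1w did not persist under T1w threshold
#> 2         5  FLAIR+T1w       below 3 mm greatest dimension
```

The ten configured lesions carry generative offsets of +0.0086 ppm and
−2.5 s⁻¹ versus white matter. Nine satisfy the FLAIR definition (one
fails the 3 mm rule) and six persist under the stringent FLAIR+T1w
definition. The recovered mean Δχ of 0.00696 ppm sits ~19% below the
generative offset — the combined shrinkage of Tikhonov regularization
at α = 0.013 and partial-volume dilution at lesion boundaries — with
the correct sign; ΔR2\* is exact on noiseless data because the
log-linear fit inverts the signal model voxel by voxel. NAWM rows sit
at the white-matter values (χ ≈ −0.03 ppm relative to reference,
R2\* = 19.2 s⁻¹), confirming the mirrored controls land in clean
tissue.

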