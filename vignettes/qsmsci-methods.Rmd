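---
title: "Quantitative susceptibility and R2* mapping of silent cerebral infarcts: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative susceptibility and R2* mapping of silent cerebral infarcts: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Silent cerebral infarcts (SCI) are small FLAIR-hyperintense white-matter
lesions found in neurologically asymptomatic people, most prominently in
sickle cell anemia. Their tissue composition is poorly characterized.
Two quantitative gradient-echo contrasts speak to it directly: magnetic
susceptibility ($\chi$, in ppm), where myelin is diamagnetic (negative)
and iron paramagnetic (positive), and the effective transverse
relaxation rate R2\* (1/s), which rises with the total load of
microscopic susceptibility sources. A lesion that is less diamagnetic
and has lower R2\* than the surrounding normal-appearing white matter
(NAWM) is consistent with demyelination or increased water content.

`qsmsci` implements the full analysis as a tested pipeline, and — since
no imaging data were deposited with the study it models — ships a
digital brain phantom whose ground truth exercises every stage:
simulate multi-echo gradient-echo (ME-GRE), FLAIR and T1-weighted
volumes; reconstruct $\chi$ and R2\* maps; segment SCI under two
threshold definitions; pair each lesion with a mirrored contralateral
NAWM region; and compute the paired statistics.

## Signal and field models

**Forward field.** A susceptibility distribution $\chi(\mathbf{r})$
shifts the static field by the dipole convolution, computed in k-space
as $\Delta B / B_0 = F^{-1}\!\left[ D(\mathbf{k}) \, F[\chi] \right]$
with

$$ D(\mathbf{k}) = \tfrac{1}{3} - \frac{k_\parallel^2}{|\mathbf{k}|^2},
\qquad D(0) = 0, $$

where $k_\parallel$ is the component along $B_0$. $D(0)=0$ is the
zero-mean (sphere-of-Lorentz) convention: a uniform susceptibility
produces no observable shift, so the uniform component is removed
before the convolution. The simulation pads the grid to twice the field
of view before convolving to suppress wrap-around, then crops; the
reconstruction operators work on the native grid, as is standard.

**ME-GRE signal.** Per voxel and echo time $t$:
$s(t) = M_0 \, e^{-R_2^* t} \, e^{i(\varphi_0 + 2\pi f t)}$, with $f$
the field in Hz ($1\ \mathrm{ppm} \leftrightarrow 127.73$ Hz at 3 T,
$\bar\gamma = 42.577$ MHz/T). Complex Gaussian noise is scaled to a
requested first-echo white-matter SNR; one seed in the acquisition
protocol governs every draw.

## Reconstruction

1. **Coil combination** (multi-coil data): per-coil constant phase
   offsets are estimated against the first coil from the first echo and
   removed; magnitudes weight the sum.
2. **Total field**: a damped Gauss–Newton fit of the complex
   mono-exponential model per voxel, initialized from the log-linear
   magnitude fit and magnitude-weighted phase increments. With echo
   spacing $\Delta TE = 4$ ms the field is identifiable only modulo
   250 Hz; estimates are reported in $(-125, 125]$ Hz.
3. **Unwrapping**: a spectral Laplacian estimate
   ($\nabla^2\varphi = \cos\varphi\,\nabla^2\sin\varphi -
   \sin\varphi\,\nabla^2\cos\varphi$, inverted with Neumann boundaries
   via mirror padding) followed by congruence restoration, so the
   output differs from the input by an exact integer number of periods
   at every voxel. This is a deliberate, documented substitute for
   region-growing unwrappers; it is exact for smooth fields and
   degrades gracefully with noise.
4. **Background removal (PDF)**: the background field is modelled as
   the dipole field of sources supported outside the brain mask and the
   best fit (conjugate gradients, tolerance $10^{-4}$, 100 iterations)
   is subtracted; the local field is demeaned over the mask.
5. **Dipole inversion**: Tikhonov-regularized least squares,
   $\hat\chi = \arg\min_\chi \|W(D\chi - f)\|_2^2 +
   \alpha\|\chi\|_2^2$, with binary mask weighting $W$, solved by
   conjugate gradients on the normal equations (tolerance $10^{-6}$,
   300 iterations). The susceptibility support is restricted to the
   brain mask: without this constraint the optimizer places sources
   outside the ROI and systematically underestimates interior contrast
   (we measured a 34% deficit on a radius-8 sphere at $\alpha=10^{-4}$;
   3% with the constraint). The default $\alpha = 0.013$; maps are
   referenced to the brain-mask mean, i.e. to within a constant of a
   water reference.
6. **R2\***: unweighted ordinary least squares of $\ln S$ on TE per
   voxel; magnitudes floored at $10^{-6}$ of the volume maximum before
   the log. No Rician correction is applied, which biases estimates at
   very low SNR.

**Choosing $\alpha$.** `lcurve_select_alpha()` sweeps a grid of
weights, records residual and solution norms, and looks for the
noise-driven corner of the log-log curve (natural cubic splines in
$\log\alpha$; the corner is the positive curvature maximum where the
solution norm starts to blow up from fitting noise). Consistent
noiseless data have no such corner, and the selector then falls back to
the smallest grid weight — nothing penalizes resolution when there is
no noise. Two caveats we measured on phantoms: the corner sits
systematically 1–1.5 decades below the truth-RMSE-optimal weight (the
well-known under-regularization bias of the L-curve), and corner
localization on coarse half-decade grids is approximate. The default
$\alpha$ is therefore a fixed protocol constant, not re-selected per
run.

## Segmentation and pairing

Seeds (generous ROIs around each visible lesion; on the phantom, the
truth masks dilated by 2 voxels) are refined in two steps on their
native grids:

- **FLAIR definition**: keep voxels with intensity
  $\ge 1.02 \times$ the mean cortical FLAIR intensity; require
  $\ge 3$ mm greatest axis-aligned extent.
- **FLAIR+T1w (stringent) definition**: additionally keep only voxels
  with T1w intensity $\le 1.02 \times$ the mean cortical T1w intensity;
  the 3 mm rule is re-checked after this step (the source protocol does
  not say whether it is; re-checking is the stricter and more
  consistent reading).

Both boundaries are inclusive at exactly $1.02\times$ the cortical
mean. ROIs are then pull-resampled (nearest neighbour, voxel-centre
convention, 0-based indices) into the GRE grid through known affines —
registration *estimation* is out of scope — and lesions reduced to 2
voxels or fewer there are excluded.

**NAWM pairing**: each lesion mask is reflected across the mid-sagittal
plane and, within the same transverse slices, shifted to the nearest
position (deterministic search, shift length then raster order, within
±20 voxels) that lies fully inside white matter and is disjoint from
every identified SCI. Voxel counts are preserved, so SCI and NAWM means
average the same number of voxels.

**Depth classes**: Euclidean distance transforms to cortex and
ventricles over white matter (a separable exact squared-distance
transform supporting anisotropic voxels, written for this package since
no installed dependency provides one in 3D). Periventricular voxels are
the ventricle-proximal 5%; juxtacortical voxels the cortex-proximal 25%
of the remainder; the rest deep; precedence periventricular >
juxtacortical > deep. The source text defines juxtacortical voxels by
the "75th percentile of the distance-to-cortex map", which selects
cortex-*distal* voxels if the map is a plain distance map; we read it
as a proximity map (cortex-proximal 25%), which matches the anatomical
meaning of juxtacortical, and expose the literal reading via
`reading = "distance"`.

**Lobes** are assigned by majority vote over an atlas; exact ties and
off-atlas ROIs go to `"other"`. The phantom uses a simple geometric
four-lobe partition (`synthetic_lobe_atlas()`), a labelled stand-in
that exercises the bookkeeping, not an anatomical parcellation.

## Statistics

Lesions are treated as independent units, as in the source analysis;
within-subject correlation among lesions is not modelled (a mixed
model would be the obvious extension). The layer wraps base R fits:

- paired $t$ (`t.test(..., paired = TRUE)`) for SCI vs NAWM means, with
  zero-variance differences flagged rather than tested;
- Bland–Altman bias and limits of agreement, bias $\pm 1.96$ sample SD;
- age correction by OLS on $\ln(\mathrm{age})$, residuals plus grand
  mean, applied pooled across groups (configurable per group);
- sequential (type-I) ANOVA in the fixed factor order
  $\ln(\mathrm{age})$, group, lobe, $\ln(\mathrm{volume})$, matching
  the reported factor set; type-II available by flag;
- Student's $t$ (two groups) or one-way ANOVA with Tukey HSD (more);
- Pearson correlations for paired ROI means and for per-subject lesion
  summaries against cognition scores (FSIQ, WMI, PSI).

All tests are two-sided; no multiple-testing correction is applied
(matching the reported analysis); excluded lesions never enter the
statistics and their reasons are exported.

## The phantom: what it emulates, and what it does not

The phantom is a nested-ellipsoid brain (cortical shell, white matter,
two CSF ventricles, two deep-grey nuclei) on the 1.15 mm isotropic GRE
grid, with FLAIR (0.65 × 0.65 × 1 mm) and T1w (1 mm) volumes rendered
on their own grids through known affines. Tissue values are
configurable with defaults $\chi$(WM) $= -0.03$, $\chi$(GM) $= 0$,
$\chi$(CSF) $= +0.02$, $\chi$(deep GM) $= +0.05$ ppm and R2\*(WM)
$= 19.2$ 1/s. The published study reports lesion measurements, not
generative tissue values, so lesion defaults are set on the reported
group contrasts — $\Delta\chi = +0.0086$ ppm and $\Delta R_2^* = -2.5$
1/s versus white matter — so that recovery tests target those numbers;
they are calibration points, not claims about lesion tissue truth.
Lesion FLAIR intensity is `flair_contrast` (default 1.25) times the
cortical mean, and exactly `t1_pass_fraction` of each lesion's T1w
voxels (up to rounding; chosen deterministically in array order) are
generated below the hypointensity threshold, so segmentation oracles
can count against the generator.

The standard ten-lesion fixture (`standard_lesion_set()`) spreads
sizes around the reported mean FLAIR lesion volume (~119 mm³) and
T1w pass fractions over $[0, 1]$, and includes one lesion below the
3 mm rule and one small lesion whose stringent-definition remnant
fails the re-checked size rule, so every exclusion path runs in a
single pipeline pass.

Not emulated: realistic anatomy, k-space artifacts, motion, flow,
slice profiles, parallel-imaging reconstruction, Rician magnitude
bias at very low SNR, and real registration error (affines are known
exactly). Passing phantom tests therefore validates the algorithmic
chain — field physics, estimators, thresholds, bookkeeping — not
robustness to real-data confounds.

## Numerical choices and degenerate inputs

- FFTs throughout; grids need not be powers of two.
- CG tolerances: inversion $10^{-6}$/300, PDF $10^{-4}$/100. PDF on
  realistic geometries typically stops at the iteration cap (the
  exterior-source normal operator is severely ill-conditioned); the
  best iterate is returned with a warning. Because truncated CG is not
  an exact projection, applying PDF twice changes the local field by a
  few percent RMS (measured 2–3%, and not reduced by 6× more
  iterations); treat the local field as an approximate projection.
  PDF also absorbs part of the harmonic dipole tail of *interior*
  sources; the effect grows with the source/mask size ratio (interior
  pattern correlation 0.97 for a radius-6 source in a radius-26 mask,
  0.85–0.93 for radius 8 in radius 20), which is acceptable for
  SCI-sized lesions deep in the brain but a known limitation for large
  sources near the mask edge.
- Empty fit voxels yield $f = 0$ and are flagged; non-converged field
  fits fall back to the weighted phase-increment estimate, flagged.
- Threshold equality: retained at exactly $1.02\times$ (inclusive on
  both contrasts).
- Mirror search ties break in raster order; the midline defaults to
  the grid mid-sagittal plane.
- Depth percentile ties follow `quantile()` type-7 interpolation.
- All randomness flows from one integer seed; re-running a config
  byte-reproduces the records.

## Problem sizes

Package tests run the full pipeline on a 64³ phantom (about 45 s on
one core) and use 32³–64³ grids for the physics oracles, 200-draw
Monte-Carlo checks for estimator bias, and 1000-rep null simulations
for type-I error; these sizes were chosen so the whole suite completes
in a few minutes while leaving the Monte-Carlo standard errors well
below the tolerances they guard.

## Known limitations

- Lesion-level inference ignores within-subject clustering.
- Tikhonov inversion at $\alpha = 0.013$ shrinks small-lesion contrast
  by roughly 10–15% on the phantom; together with partial-volume
  dilution from nearest-neighbour ROI transfer, end-to-end recovered
  $\Delta\chi$ sits ~15–20% below the generative offset (R2\*, fitted
  voxelwise from magnitudes, is exact on noiseless data).
- The L-curve corner under-regularizes relative to the truth-RMSE
  optimum (see above); it is a guide, not an oracle.
- The Laplacian unwrapper can leak errors across narrow mask bridges
  where a region-growing unwrapper would not.
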