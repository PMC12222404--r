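---
title: "Methods: voxel dosimetry and learned corrections for Y-90 bremsstrahlung SPECT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel dosimetry and learned corrections for Y-90 bremsstrahlung SPECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosekit)
```

## The problem

After selective internal radiation therapy (SIRT), the distribution of
Y-90 microspheres in the liver is imaged by bremsstrahlung SPECT (bSPECT).
Quantitative voxel dosimetry on those images requires attenuation
correction (AC) and scatter correction (SC) at reconstruction time; the
fully corrected state is denoted ASC, the uncorrected state NC. When a
co-registered CT is unavailable or corrections were not applied, the dose
maps are biased: tumours are underdosed and normal liver overdosed without
scatter correction, and superficial tissue is overdosed without
attenuation correction. `dosekit` implements the full chain needed to
study and correct these biases — calibration, local-energy-deposition
dosimetry, a synthetic phantom generator that reproduces the degradation
structure, a trainable image-to-image correction engine, and the
evaluation battery (voxel metrics, 3D gamma analysis, DVHs, region
dosimetry, rank-sum comparisons).

## Dosimetry model

### Local energy deposition (LDM)

The LDM assumes microspheres are permanently trapped (no biological
clearance) and that all beta energy is absorbed in the voxel of decay (no
crossfire). For activity $A(v)$ (MBq) in a voxel of mass $m$,

$$D(v) = A(v)\,\frac{T_{1/2}}{\ln 2}\,\bar E \,/\, m,$$

with defaults $T_{1/2} = 64.1$ h, $\bar E = 0.93$ MeV per decay, and a
uniform tissue density of 1.05 g/cm$^3$ (nuclear-data compilations also
quote 0.937 MeV; the constant is configurable through
`radionuclide_params()`). The closed form for 1 GBq spread uniformly over
1 kg of tissue is 49.6 Gy in every voxel, which the test suite asserts to
a relative $10^{-3}$.

Density is uniform everywhere, including lungs; a density map could be
attached at the calibration step, but the default mirrors the single
stated liver density. Dose outside the whole liver (WL) is computed with
the same scale factor, so lung, kidney and stomach doses come from the
same map.

### Calibration

Two calibrations exist side by side:

* **Phantom conversion factor** (`phantom_conversion_factor()`): from a
  uniform 6200 mL cylinder holding 605.33 MBq, counted over the central
  70% of the phantom. The central ROI is obtained by isotropic erosion of
  the phantom mask until its volume is at most the requested fraction
  (ties broken toward the smaller ROI) — vendor documentation does not
  specify the construction. The factor is reported for auditability but
  not used in patient dosimetry.
* **Patient-relative calibration** (`patient_count_to_activity_scale()`):
  the count map is scaled so total WL activity equals the net injected
  activity. This removes any dependence on scanner sensitivity,
  acquisition time, and calibration-geometry mismatch, and it forces
  exact WL energy conservation:
  $\sum_{WL} D\,m = A_{inj}\cdot \frac{T_{1/2}}{\ln 2} \cdot \bar E$,
  which the suite verifies to relative $10^{-10}$. A consequence used
  throughout: NC/AC/ASC dose maps of the same case deposit identical
  total energy in the WL and differ only in spatial distribution.

"Net injected activity" is a single scalar; residual-vial modelling and
decay correction between assay and scan are the caller's responsibility.

## Synthetic phantoms

`phantom_recipe()` parameterises a liver-centred piecewise-constant
activity distribution on a SPECT-like grid (default $128^3$ at 4.795 mm
isotropic; the desk profile uses $48^3$): ellipsoidal body, liver, lungs,
kidneys and stomach, spherical tumour(s) with an uptake ratio above one
(default 5:1, tumour-avid as with glass microspheres), a small body
background (1% of liver concentration) and an optional 2% lung shunt.
The segmentation invariants (tumour ⊆ WL ⊆ body, WNL = WL minus tumour)
hold by construction and are validated.

`degradation_model()` supplies the stand-in physics for what the
reconstruction corrections remove:

* **Attenuation**: each voxel is attenuated by the mean over a fan of
  in-plane ray directions spanning 180° (default 16 directions; 64
  mirrors a clinical acquisition) of $\exp(-\int \mu\,dl)$ from the voxel
  to the body surface. Defaults $\mu_{soft} = 0.011$, $\mu_{lung} =
  0.003$, $\mu_{bone} = 0.017$ mm$^{-1}$ are broad-spectrum bremsstrahlung
  effective values chosen as documented stand-in constants. The line
  integral uses a half-voxel trapezoid recurrence marched slice by slice,
  so a single axis-aligned direction through uniform $\mu$ reproduces
  Beer–Lambert exactly with depth measured from the voxel centre.
* **Scatter**: a fraction $f$ (default 0.35, the middle of the 30–40%
  clinically observed for photopeak-window bremsstrahlung) is
  redistributed by a broad Gaussian (default FWHM 30 mm, deliberately
  much broader than a reconstruction filter so scatter and resolution
  effects stay distinguishable). The blurred component is renormalised to
  the input total, making the operation count-conserving *by
  construction* rather than approximately so under a padding convention —
  photopeak-trapped scatter redistributes counts, it does not remove
  them.
* **Poisson noise** enters at the count level (default total 2·10^6
  detected counts per acquisition), before calibration, where counting
  noise physically arises.

The triplet generator emits ASC (true activity), AC (scatter only) and NC
(attenuation then scatter); the scanner family modelled here cannot
scatter-correct without attenuation-correcting, so no attenuation-only
state exists. What the phantoms do **not** emulate: reconstruction
artefacts of OSEM, collimator-detector response, bremsstrahlung spectral
effects, metal implants, air interfaces, or anatomical variability beyond
ellipsoid jitter. Passing tests therefore demonstrate correctness of the
chain and recoverability of this degradation structure — not clinical
performance on patient data.

## The correction engine

The three tasks map correction states exactly as their names suggest: AC
(NC→AC), SC (AC→ASC, i.e. the scatter correction), ASC (NC→ASC). Every
dose map carries its correction state, and state mismatches between a
dataset and a task always raise — the contract is total.

Training follows the standard protocol: dose maps normalised by 200 Gy
without clipping (so 400 Gy maps to 2.0 and the inverse is exact), random
cubic patches (64³ at full scale) with identical random 90° rotations and
axis flips applied to both members of a pair (no deformable augmentation,
which would corrupt quantitative values), Adam with learning rate
1·10⁻³, decoupled weight decay 1·10⁻⁴, batch size 2, L1 loss, 200 epochs,
dropout 0.1, and five-fold cross-validation with deterministic
round-robin fold assignment (fold sizes differ by at most one; 148 cases
split 30/30/30/29/29). Inference tiles the volume with training-size
windows at 50% overlap, averages overlaps uniformly, averages the five
fold members voxelwise (a running mean, so an ensemble of identical
members is *exactly* the single-member output), denormalises, and clamps
at zero. Gaussian-weighted window blending was considered and rejected:
with voxelwise members it is equivalent, and with general members uniform
averaging keeps the seam-freeness contract testable at $10^{-6}$.

### The default regressor

The regressor slot is pluggable behind a fit/predict contract; at full
scale a volumetric attention network would occupy it. The shipped default
(`regressor_voxfeat()`) is a physics-guided voxelwise linear model: the
prediction is a learned linear combination of six channels computed from
the input volume — the raw value, a fine blur, the nominal forward
scatter operator, an inverse-attenuation channel $x/a(v)$ (with $a(v)$
the mean in-plane Beer–Lambert factor through the image support at a
nominal soft-tissue $\mu$), the scatter-deconvolved variant (three
Neumann fixed-point iterations of the nominal scatter model) divided by
$a$, and the full deconvolve–correct–rescatter chain. Channels involving
$a$ are rescaled per case to the input's high-uptake total, mirroring the
patient-relative calibration applied downstream. Members are initialised
at identity, so an untrained member is a no-op, and trained with the same
Adam/L1/weight-decay/dropout loop as any other member. Which channels
matter for a task — and with what weights — is learned from the data.

The desk profile (`desk_training_config()`) uses 32³ patches, 10 epochs
and a step size of 0.01 suited to a six-parameter member; the full
protocol values ship as the `training_config()` defaults.

## Evaluation battery

* **Voxel metrics** (`voxel_report()`): ME, MAE, MSE, RMSE, PSNR (data
  range = in-mask reference maximum; the range convention is recorded in
  the report), SSIM (7³ uniform window, $k_1 = 0.01$, $k_2 = 0.03$ on
  the in-box reference range, computed over the mask bounding box with
  full windows only), RE and RAE. RE/RAE use the global sum-ratio form;
  the per-voxel form explodes at near-zero reference voxels and is
  available via a flag with a 0.1 Gy floor. Both decisions are recorded
  in every report. The default evaluation mask is the body, so agreement
  on empty background is not rewarded.
* **Joint histograms** (`joint_histogram_fit()`): 2D histogram for
  plotting; slope/intercept/R² from ordinary least squares on the raw
  voxel pairs, never on binned counts.
* **3D gamma** (`gamma_map()`): global normalisation by the reference
  maximum is the default (the dominant convention when unstated; local
  mode available), trilinear sub-voxel search on a ⅓-voxel refinement
  grid, search radius $2\cdot$DTA with $\gamma$ capped at 2 (capped
  voxels count as failures, so pass rates are unaffected by the cap), and
  no low-dose threshold by default (whole-image pass rates near 97% in
  clinical reports imply background voxels were included; a threshold is
  configurable and recorded per run). The optimised implementation visits
  candidate offsets sorted by distance and stops once the spatial term
  alone exceeds the running minimum; the suite proves equivalence with an
  exhaustive brute-force scan to $10^{-9}$ on seeded volumes, and
  monotonicity of pass rates across the 4.795 mm/1%, 10 mm/5%,
  15 mm/10% criteria triple.
* **Region dosimetry** (`region_report()`, `dvh()`): MAD with across-voxel
  SD, region ME/MAE, region RE as the MAD ratio (scale-stable), RAE =
  |RE|, and median shift defined as the difference of medians (the
  difference-of-medians choice is recorded in the report). DVHs are
  cumulative with a 0.5 Gy default step; V(0) = 100%, monotone
  non-increasing, and the layer-cake integral recovers the MAD within one
  bin width.
* **Distribution comparison** (`compare_mad_distributions()`): two-sided
  Mann-Whitney U with tie correction at $\alpha = 0.05$.

### What the synthetic cohort can and cannot reproduce

The qualitative bias pattern — tumour underdosed and WNL overdosed on
uncorrected maps, case by case — is reproduced and asserted. The
clinical observation that tumour MAD differs significantly between
uncorrected and corrected maps *while WNL MAD does not* is a property of
a heterogeneous patient cohort, where inter-patient variability swamps
the small WNL shift; at matched synthetic geometry both regions separate
statistically, and with fully randomised geometry neither does at small
n. The suite therefore asserts the per-case sign pattern and tumour
separability, and leaves cohort-significance patterns out of scope.

## Numerical choices and degenerate inputs

* Grid convention: 0-based voxel indices, world = origin + index ×
  spacing, identity direction (RAS); NIfTI-1 is the canonical format
  (spacing/origin round-trip at the header's 32-bit float precision),
  MetaImage is accepted on read and written at full double precision.
* Resampling treats dose and count-concentration values as intensive
  (plain interpolation); an extensive flag multiplies by the voxel-volume
  ratio for count preservation. Dose maps stay on the SPECT grid;
  nothing is resampled to CT geometry.
* Body masking: threshold at 1% of the 99.9th-percentile value, largest
  26-connected component, one closing pass with a 1-voxel ball.
* All-zero images yield an empty-mask warning; empty regions are skipped
  with a warning; a constant reference makes the joint-histogram fit an
  error, and a zero reference sum makes relative metrics an error rather
  than NaN.
* Identity metric values are exact by construction (SSIM returns 1 for
  identical inputs before any windowing; PSNR reports `Inf` as the
  sentinel for a zero-MSE comparison).
* Every stochastic stage (phantom noise, fold assignment, patch
  sampling, dropout) derives its stream from an explicit integer seed,
  and reruns are bit-identical.

## Problem sizes

The package's test and demonstration profile simulates twelve $48^3$
phantoms at 4.795 mm spacing with an 80/20 split, trains all three tasks
with the five-fold ensemble, and evaluates on the held-out cases; this
was chosen as the smallest cohort on which the correction recovery (a
≥25% held-out MAE reduction per task) is stable across seeds. Gamma
oracle-equivalence checks run on $\le 20^3$ volumes where the exhaustive
scan is tractable.

## Known limitations

* The degradation model is an image-domain stand-in: no projection-space
  reconstruction, no collimator response, no spectral modelling.
* The default regressor is linear in its physics-guided channels; it
  cannot express corrections outside that span (e.g. around metal
  implants or air interfaces), and its inverse-attenuation channel
  assumes a single nominal soft-tissue $\mu$.
* Uniform density biases lung dose; organ SDs are across voxels unless a
  cohort table is requested, where across-patient SDs are labelled.
* Count-domain training is reachable by feeding count maps with a
  different normalisation constant, but no performance claims attach to
  it.
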