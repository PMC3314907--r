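---
title: "Local perturbation fields in DTI: model, estimation and correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local perturbation fields in DTI: model, estimation and correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpfdti)
```

## The problem

Diffusion tensor imaging infers a symmetric tensor $D(r)$ per voxel from
diffusion-weighted (DW) signals, via the linear relation between the
attenuation and the experimental design matrix,

$$\ln\frac{S_0}{S_i(r)} = B_i : D(r), \qquad B_i = b\, g_i g_i^{\mathsf T},$$

with $b$ the diffusion weighting (s/mm$^2$) and $g_i$ the unit gradient
direction. The apparent diffusion coefficient along one direction is
$\mathrm{ADC}_i = \ln(S_0/S_i)/b$. Scalar index maps — mean diffusivity
$\mathrm{MD} = \operatorname{tr}(D)/3$ and fractional anisotropy
$\mathrm{FA}$ — are the quantities used in practice.

The gradient actually played out during diffusion weighting deviates from
the requested one: eddy currents, coil nonuniformity, amplitude
mis-calibration, concomitant fields and imaging/diffusion cross terms all
contribute. To first order this deviation is a spatially varying linear
map, the *local perturbation field* (LPF) matrix $\Sigma(r)$:

$$g_i^*(r) = (I + \Sigma(r))\, g_i .$$

Using the nominal $B_i$ on data acquired with $g_i^*$ biases the fitted
tensor. To first order the measured tensor is

$$D^*(r) = L^\Sigma(r)\, D(r), \qquad
  L^\Sigma = I + 2\Sigma^+, \qquad
  \Sigma^+ = \tfrac{1}{2}(\Sigma + \Sigma^{\mathsf T}),$$

so only the symmetric part of $\Sigma$ is observable in, and needed to
correct, tensor data. $L^\Sigma$ (the *LPF ellipsoid*) is symmetric and
positive definite for small perturbations. Because $L^\Sigma D$ is not
itself symmetric for anisotropic $D$, the package returns the symmetrized
product $(LD + DL)/2$; every scalar observable $B : D^*$ is unchanged by
this choice (trace cyclicity), and fitted tensors are symmetric by
construction. (The antisymmetric part of $\Sigma$ enters only as the
commutator $[D, \Sigma^-]$, which rotates eigenvectors at first order but
leaves eigenvalues, MD and FA untouched; it is neither estimable from
tensor data nor needed for index-map correction.)

In the isotropic-diffusion limit $D = D_0 I$ the measured tensor is simply
$D_0 L^\Sigma(r)$: the trace map of $L^\Sigma$ marks regions of MD bias
and its FA map marks regions of FA bias in any human index map. This is
also what makes a water phantom the natural calibration object.

## Two-step estimation from a water phantom

Water has a single, isotropic diffusion coefficient $D_w$, so phantom DWI
under a perturbation satisfies
$\ln(S_0/S_i)(r) \approx D_w\, (L^\Sigma(r) B_i) : I$ and a standard
voxelwise tensor fit of the phantom returns $D_w L^\Sigma(r)$
(`voxelwise_ellipsoid()`). The pipeline (`estimate_lpf()`) then:

1. smooths the phantom DWI (5-mm FWHM Gaussian by default) and masks it
   (threshold at 30 % of the robust maximum of the mean $b=0$ image,
   eroded by 2 voxels — edge voxels violate the smoothness assumption and
   carry partial-volume bias after smoothing);
2. fits a tensor per voxel, keeping the per-voxel residual variance;
3. determines $D_w$ as the median MD in a central 15-mm ROI (the
   perturbation is minimal near the isocentre; a temperature-calibrated
   value can be supplied instead);
4. converts to $\Sigma^+(r) = (L^\Sigma(r) - I)/2$ and fits each of the
   six unique elements with a 3rd-order *regular real solid harmonic*
   expansion (16 coefficients per element) by weighted least squares,
   weights $w(r) = 1/(\sigma^2_{\text{resid}}(r) + \varepsilon)$,
   $\varepsilon = 10^{-12}$.

The residual-variance weights implement the model's own robustness
argument: artefacts not proportional to the diffusion gradient (vibration,
ghosting, flow) do not bias the tensor-space estimate but inflate the fit
residual, so down-weighting by residual variance suppresses exactly those
voxels.

Solid harmonics — harmonic polynomials $r^l Y_{lm}(x, y, z)$ — rather than
surface harmonics on a fixed sphere, because gradient-coil fields are
conventionally expanded that way and must be evaluated at arbitrary radii.
Coordinates are world-mm from the NIfTI affine (the field lives in the
scanner frame — this is what makes repositioning experiments meaningful),
shifted by the model origin (assumed isocentre) and scaled by a
characteristic radius $R_\mathrm{ref} = 150$ mm for conditioning. The
basis is unnormalized with a documented $(l, m)$ ordering; any fixed
convention works because coefficients never leave the model file.

## Correction

`correct_tensor()` / `correct_dataset()` invert the first-order relation,
$D = \mathrm{sym}\!\left((L^\Sigma)^{-1} D^*\right)$, in two modes:

* `diag` — $L = I + 2\,\mathrm{diag}(\Sigma)$, using only perturbation
  gradients parallel to the applied gradient;
* `full` — $L = I + 2\Sigma^+$, the whole symmetric matrix.

Voxels where $L$ is not positive definite are out of the linear regime;
they are passed through uncorrected and counted rather than silently
"corrected". An alternative route (`refit = TRUE`) perturbs each voxel's
B-matrices with `perturb_b_matrix_linear()` and refits the tensor; the two
routes agree to first order and the tensor-space route is the default
because it avoids a per-voxel refit.

For grey/white-matter contrast, `fa_contrast()` implements
$\Delta \overline{FA}_\mathrm{cont} = \overline{FA}^{WM}_{ROI} -
\overline{FA}^{GM}_{ROI}$; perturbations bias small (grey-matter) FA
upward, lowering this contrast, and full-matrix correction restores it.
Segmentation itself is out of scope — masks are consumed as thresholded
probability maps.

## The synthetic phantom and what it does (not) emulate

`sim_config()` fixes the study conditions: a 48³ grid of 2.3-mm isotropic
voxels, a spherical phantom of radius 80 % of the half-FOV, $b = 1000$
s/mm$^2$, 60 quasi-uniform (Fibonacci-sphere) directions plus 6 $b=0$
volumes, $D^\mathrm{sim} = \ln(5)/b \approx 1.61\times10^{-3}$ mm$^2$/s so
the DW/non-DW signal ratio is exactly 1/5, additive Gaussian noise at SNR
50 ($b=0$) and 10 (DW, measured against the mean in-phantom DW signal),
and 5-mm FWHM smoothing before re-estimation. The grid is smaller than a
real 96² × 60 acquisition matrix; the estimation error is bias-dominated
(see below), so this mainly buys runtime, and the grid is configurable.

`random_lpf()` draws the six $\Sigma^+$ elements as independent 3rd-order
expansions with coefficients uniform on $[-1, 1]$, then rescales the whole
field so the maximum element-wise peak-to-peak variation over the phantom
equals the configured amplitude (0.1 by default; a per-element variant is
available). The draw happens on a basis whose columns are normalized to
unit maximum magnitude over the phantom: on the raw $R_\mathrm{ref}$-scaled
basis the $l=0$ constant dominates a uniform draw, and because a constant
offset is invisible to peak-to-peak normalization the field would end up
with $|\Sigma| \approx 0.25$ — far outside the small-perturbation regime
that "10 % of the nominal gradient" describes. Column normalization makes
every harmonic order contribute comparably and keeps
$|\Sigma| \lesssim 0.08$ at amplitude 0.1.

`synthesize_phantom()` uses the *exact* forward model by default: the
effective gradient $g^* = (I+\Sigma)g$ changes the b-value by $|g^*|^2$,
quadratic terms included. The estimator is what is linear — so the
Monte-Carlo measures the estimator's linearization error along with its
noise sensitivity. A `forward = "linear"` option synthesizes from the
first-order perturbed B-matrix instead, under which full correction with
the true field is exact to machine precision; tests use it to separate the
two error sources.

What the simulation does *not* emulate: EPI readout distortion, motion,
Rician noise floors (the noise is Gaussian, as in the reference protocol;
SNR 10 is the regime where that is still defensible), cardiac pulsation,
vibration/ghosting artefacts, and non-Gaussian diffusion. Passing tests
therefore show correctness of the perturbation model and estimator under
its own assumptions, not robustness to every real-scanner artefact.

## Precision metric and known numerical behaviour

`delta_epsilon()` compares true and estimated fields element-wise: per
voxel the modulus of the difference divided by the average of the two
moduli, averaged over the mask (the symmetric normalized mean difference;
for $est = (1+\alpha)\,true$ it equals $\alpha/(1+\alpha/2)$ exactly).
The ratio-of-means alternative (mean absolute difference over mean
modulus) was considered and measured: on the same estimates it reads
substantially lower — typically by a factor of two to three at the default
study conditions — because it does not weight zero-crossing regions of the
field. The per-voxel form is the conventional reading of "normalized mean
difference" and is the one reported by `monte_carlo()`; the test suite
computes both on a common run to document the gap.

Two floors are worth knowing:

* **Linearization floor.** The voxelwise estimate of $L^\Sigma$ from exact
  signals is $I + 2\Sigma + \Sigma^2$, so the recovered $\Sigma^+$ carries
  a $\Sigma^2/2$ bias that no amount of SNR removes. It hits the diagonal
  elements hardest (each collects a sum of squares of a whole row of
  $\Sigma$) — this is the main reason diagonal elements are estimated
   roughly 2–3× worse than off-diagonal ones, and it scales quadratically
  with amplitude (verified by amplitude-halving in the tests).
* **Correction floor.** Correcting exact-forward data with the *true*
  field leaves residual anisotropy of order $|\Sigma|^2$, a few $10^{-3}$
  in FA at amplitude 0.1. Under the linear forward model the same
  correction is exact to $10^{-12}$.

Degenerate inputs: non-positive signals are flagged invalid and excluded
from fits (not errors); rank-deficient direction sets or single-slice
spatial sampling raise errors naming the deficiency; negative or
degenerate eigenvalues are preserved in fitted tensors (corrections
operate on the raw fit); eigenvector signs follow a
first-nonzero-component-positive convention; `FA` of the zero tensor is
defined as 0.

## Design choices that were genuinely open

* The tensor fit is ordinary least squares on attenuations with optional
  per-direction weights; nothing in the reference pipeline requires a
  noise-weighted scheme at this step, and OLS keeps the voxelwise stage a
  pure linear solve. ADCs are computed against the mean of all $b=0$
  volumes.
* $D_w$ normalization uses the central-ROI median (robust to the ~10 %
  corrupted-voxel level tested) rather than a mean or an external value,
  with a user override for calibrated values.
* Harmonic orders above 3 are not offered: gradient-coil and eddy-current
  fields are conventionally described to 3rd order, and none of the
  validation exercises higher orders.
* bval/bvec follow the FSL dialect; directions are rotated to world
  coordinates by the rotational part of the NIfTI affine on reading, since
  the perturbation model lives in the scanner frame.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(grid_dim = 32)          # desk-scale grid
truth <- random_lpf(cfg, seed = 1)
phantom <- synthesize_phantom(truth$sigma, cfg, seed = 2)

fit <- estimate_lpf(phantom$dwi, phantom$scheme, phantom$affine,
                    mask = "auto", dw = "auto")
est <- evaluate_lpf(fit$model, cfg$dim3, cfg$affine, fit$mask)
round(delta_epsilon(truth$sigma, est), 3)

res <- correct_dataset(phantom$dwi, fit$model, mode = "full",
                       scheme = phantom$scheme, affine = phantom$affine,
                       mask = fit$mask)
mean(res$fa, na.rm = TRUE)
```

A full Monte-Carlo run at the study conditions is
`monte_carlo(25, sim_config(), seed = 1)` (a few minutes on one CPU);
its pooled medians are the quantities `scripts/acceptance.R` reports.

## Limitations

The model is first order: non-linear gradient response (e.g. asymmetric
$\pm x$ mis-calibration) is outside its reach, and at peak-to-peak
amplitudes well beyond 0.1 the quadratic floors grow accordingly. The
estimated field is acquisition-specific — slice prescription, timing and
gradient amplitudes all enter $\Sigma$ — so a phantom calibration is only
valid for the matching human protocol. Readout-period perturbations
(image distortions) are a separate problem handled by registration tools,
not here.
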