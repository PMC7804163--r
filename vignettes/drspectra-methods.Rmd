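---
title: "Methods: models, parameters and design choices in drspectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in drspectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`drspectra` implements a complete, testable analysis chain for fiber-probe
diffuse reflectance spectroscopy (DRS) of soft tissue, of the kind used to
discriminate tumor from normal mucosa in the colorectal wall:

1. **Preprocessing** — calibration of raw three-channel intensities,
   stitching of visible (VIS) and near-infrared (NIR) spectrometer channels,
   min-max feature scaling, wavelength-range selection.
2. **Classification** — soft-margin kernel SVMs evaluated by repeated
   stratified twofold cross-validation with sensitivity, specificity,
   accuracy and AUC.
3. **Probed-depth estimation** — Monte Carlo photon transport in a
   semi-infinite turbid medium, photon-hitting-density (PHD) maps for a
   source-detector fiber pair, and the depth of the PHD maximum under the
   fiber midpoint.
4. **Synthetic data** — a chromophore-based generator that emulates the
   statistical structure such clinical datasets have (two classes, two probe
   geometries, per-patient and per-site variability), so that every stage is
   testable without patient data.

Deliberately out of scope: the inverse extraction of optical properties from
measured spectra (optical-property tables are user-supplied or synthetic),
layered-tissue transport, GPU acceleration, and classifier families other
than SVM.

# Preprocessing model

Calibration forms the dimensionless ratio

$$R(\lambda) = \frac{I_{tissue} - I_{background}}{I_{reference} - I_{background}},$$

with an error (naming the wavelength) whenever the denominator is
non-positive, and no clipping. The identity is exactly invariant to any
positive gain applied to all three channels, which is why the lamp and
detector response cancel.

The VIS (≈350–1130 nm) and NIR (≈1095–1919 nm) channels overlap on
1095–1130 nm. The merged spectrum equals VIS below and NIR above the
overlap; inside it the channels are cross-faded with a weight index
$i = 0..100$, giving $((100-i)R_{VIS} + i\,R_{NIR})/100$. One numerical
choice deserves a note: combining on an intermediate 101-point grid and then
re-interpolating onto the output grid would add an $O(h^2)$ resampling error
(~$10^{-6}$ relative on smooth absorption bands). The package therefore
evaluates the same cross-fade with a continuous weight index directly at the
output wavelengths. The two formulations agree exactly at each of the 101
points; the continuous one is also exactly continuous at the overlap edges
and keeps the calibrate→merge round-trip on noiseless synthetic data exact
to floating-point precision, which the tests rely on.

"Centered and scaled between −1 and +1" is implemented as midrange /
half-range (min-max) scaling, the only scaling that guarantees the stated
bounds: per wavelength, offset $=(\max+\min)/2$ and half-range
$=(\max-\min)/2$ are computed **on the training rows only** and applied to
all rows. Held-out values may legitimately fall outside $[-1, 1]$ and are
not clipped; constant features map to 0. Fitting the scaling per training
fold (rather than once on the full dataset) prevents information leakage
into the test folds; a full-dataset mode exists behind
`scale_within_folds = FALSE` for comparison.

Wavelength selection uses closed intervals and, for discrete requested
wavelengths, the single nearest grid column with ties broken toward the
lower wavelength.

# Classification and evaluation

The soft-margin kernel SVM is solved in its standard dual by sequential
minimal optimization (maximal-violating-pair working-set selection, KKT
tolerance $10^{-6}$ by default) in compiled code; the decision function is
$f(x) = \sum_i y_i \alpha_i K(x, x_i) + w_0$. (The source material's printed
decision function writes $y_i C_i$ where standard theory has the dual
coefficients $\alpha_i$, and its kernel-identity line is garbled; the
standard dual is what is implemented.) Kernels:

* polynomial of order $p \in \{1,2,3\}$: $(\langle x_1/s, x_2/s\rangle+1)^p$
  with kernel scale $s$, by default the median pairwise Euclidean distance
  over a seeded subsample of ≤1000 training rows (a documented, reproducible
  stand-in for MATLAB's undocumented subsampling heuristic);
* Gaussian: $\exp(-\|x_1-x_2\|^2/(2\sigma^2))$ with $\sigma \in
  \{0.5, 2, 8\}$ for the fine/medium/coarse variants, applied directly in
  the exponent.

The penalty strength is $C = 1$ for all six standard configurations.

Evaluation is repeated stratified twofold cross-validation: per iteration
the data are split into equal halves (stratified by class, since a random
non-stratified split can degenerate at small n; a non-stratified mode
exists), the model is trained on one half and scores the other, the halves
are swapped, and the pooled predictions — each sample predicted exactly
once — yield one set of metrics per iteration. Means and SDs over 10
iterations are reported. AUC is computed from the continuous decision
values as the tie-corrected pairwise concordance probability (equal to the
trapezoidal ROC area). Splits are keyed to stable sample ids, so results do
not depend on dataset row order. Tumor is the positive class (+1)
throughout. No multiple-testing correction is applied; the across-iteration
SDs are the only dispersion reported.

# Monte Carlo probed depth

Photon packets perform the standard variance-reduced random walk for a
single semi-infinite homogeneous layer: specular deduction
$((\eta_{rel}-\eta_{out})/(\eta_{rel}+\eta_{out}))^2$ at launch under a
pencil beam, exponential steps $-\ln\xi/(\mu_a+\mu_s)$, weight drop
$\mu_a/(\mu_a+\mu_s)$ scored into cylindrical $(r,z)$ bins of 50 µm over a
5 × 5 mm grid, Henyey–Greenstein scattering with $g = 0.9$, unpolarized
Fresnel reflection (with total internal reflection) at the boundary for
$\eta_{rel} = 1.4$ against $\eta_{out} = 1$, and Russian roulette below
weight $10^{-4}$ with survival probability 0.1. Fluence is absorbed weight
per bin divided by (bin volume × $\mu_a$ × photons launched).

Bookkeeping is exact by construction: the roulette ledger records the *net*
weight change (killed minus injected into survivors), so specular + diffuse
+ absorbed (in and beyond the grid) + roulette-net + step-cap loss equals 1
to floating-point rounding — a stronger property than the $10^{-3}$
expectation-level closure the tests assert. At $\mu_a = 0$ the walk's
z-component is recurrent but has infinite expected path length, so a step
cap with a tracked "lost" bucket is required; the truncation loss shrinks
roughly as the inverse square root of the cap.

The radially resolved escape weight doubles as an estimate of diffuse
reflectance $R_d(\rho)$, validated against an independently implemented
extrapolated-boundary diffusion dipole (isotropic source at
$z_0 = 1/\mu_t'$, image source across the extrapolated boundary
$z_b = 2AD$, internal-reflection parameter $A$ from the Groenhuis
polynomial). Agreement is within 15% at $\rho = 2.5$ mm for
$\mu_a = 0.01\,\mathrm{mm}^{-1}$, $\mu_s' = 1\,\mathrm{mm}^{-1}$; the
residual ~10–15% bias at a few transport mean free paths is the known
accuracy limit of the dipole model near its validity boundary, not Monte
Carlo error: the walk itself reproduces the exact Chandrasekhar H-function
half-space albedo (0.41502 for a matched isotropic medium at single-scatter
albedo 0.9) to Monte Carlo precision.

PHD maps use reciprocity: one simulation serves as both source and detector
fluence map (the fibers are identical; whether the original analysis
simulated each collection fiber separately is unknowable from the text).
One regime boundary is worth knowing: "a larger source-detector distance
probes deeper" holds for tissue-like transport, but when strong absorption
meets dense scattering (around $\mu_a \gtrsim 0.5\,\mu_s'$ at short
transport mean free paths, e.g. $\mu_a = 1$, $\mu_s = 20\,\mathrm{mm}^{-1}$)
the surviving photon paths collapse toward the source-detector chord and the
PHD maximum under the midpoint no longer moves deeper with SDD — converged
simulations show it at or slightly above the small-SDD depth. The
acceptance property sets therefore pair strong absorption with sparse
scattering so that every set exercises the geometry the claim is about.

The Cartesian 3.75 mm × 5 mm map is centered on the fiber midpoint with an
odd bin count so a bin center lies exactly at the midpoint; radial values
are interpolated linearly between cylindrical bin centers, constant inside
the innermost center, zero beyond the grid. The probed depth is the bin
center of the maximum PHD value in the midpoint column, ties toward the
surface. Fiber diameter and numerical aperture are not modeled (pencil
beam); the photon budget default is $10^5$–$10^6$ per wavelength with the
original $10^7$ available by argument.

# Synthetic data generator

The generator states a world; its defaults are fixed, not tuned per test.

**Absorption bases** are sums of Gaussian bands plus smooth baselines with
the canonical band positions (hemoglobin Soret/Q bands at 420/540/580 nm,
deoxyhemoglobin 430/555/760 nm, water 970/1200/1450/1940 nm, lipid
930/1210/1730 nm, monotone collagen term). Band *positions* are fixed by
tissue optics; the numeric shapes are a generator choice rather than
literature extinction tables, keeping the package free of downloads.
Scattering follows $\mu_s(\lambda) = a(\lambda/800\,\mathrm{nm})^{-b}$ with
$g = 0.9$.

**Forward model.** Reflectance at the probe SDD is the diffusion dipole
evaluated at $\rho = SDD$. In strong water bands $\mu_a$ can exceed
$\mu_s'$, where the diffusion approximation is formally invalid; a note is
emitted and values are returned (the resulting band shapes are qualitatively
correct — deep dips — which is all the classifier consumes). The full MC
module is *not* used for bulk generation: depth analysis needs it, spectra
generation only needs a smooth, monotone-in-$\mu_a$ forward map.

**Depth contrast.** Each class has a superficial (mucosal) and a deep
(submucosal) chromophore model, mixed with an SDD-dependent weight
$w_{deep} = SDD/(SDD + 2000\,\mu m)$ (0.24 at 630 µm, 0.56 at 2500 µm): a
large-SDD probe sees proportionally more of the deep compartment. This is a
deliberate caricature of layered transport — the generator is not a layered
radiative-transport model — but it lets the pipeline reproduce the
qualitative finding that a larger SDD classifies better when the diagnostic
contrast lies deep (`deep_contrast_specs()`, where only the deep models
differ between classes).

**Variability and noise.** Per-patient and per-site relative jitters
(default SDs 0.15 and 0.07) multiply each chromophore concentration and the
scattering amplitude; negative excursions are clamped at zero and logged,
and jittered water+lipid volume fractions are rescaled if they exceed 0.98.
Intensity noise is multiplicative Gaussian (default SD 0.03, a
shot-dominated-regime approximation) on the tissue channel; the background
is constant, and the lamp × detector response is one smooth positive curve
shared by the tissue and reference channels so that it cancels exactly under
calibration, as in the real instrument.

**Calibration of the class contrast.** The clinical effect sizes are not
published, so the tumor-minus-normal parameter deltas and the variance
components were calibrated *once*, before the acceptance tests were frozen,
so that the default world yields a quadratic-SVM cross-validated AUC near
the mid-0.9s at the 630 µm SDD (≈0.975 measured during calibration),
matching the scale of the reported clinical performance; no claim of
equivalence is made. Two known departures of the default world from the
clinical data: (i) at the default contrast the large SDD scores slightly
*lower* than the small one — the reported small<large ordering emerges here
only in the deep-contrast configuration; (ii) a green classifier test
establishes that the pipeline machinery is sound on data with this
covariance structure, not that real colorectal spectra are this separable.
Patient structure defaults to 14 patients × 15 sites per class, echoing the
typical per-specimen site counts of such studies.

# Reproducibility

Every stochastic stage takes a mandatory integer seed; the Monte Carlo uses
a self-contained xoshiro256++ generator, so MC results are bit-reproducible
and independent of R's RNG state, and the generator and CV save/restore
R's RNG. Pipeline stage seeds are derived from the master seed by a pure
hash of the stage name (`derive_seed()`), so stages can be re-run
independently. Re-running the demo pipeline with one master seed reproduces
every artifact hash bit-identically.

# Known limitations

* The generator's spectra live on the diffusion approximation; absolute
  reflectance values in strong absorption bands are qualitative.
* Two-layer depth contrast is emulated by model mixing, not by layered
  transport.
* Met-hemoglobin, bile, bilirubin and β-carotene bases are not implemented.
* The MC is single-layer, steady-state, pencil-beam; no fiber geometry.
* `evaluate_cv` supports k ≥ 2 folds but the protocol of record is twofold
  with swap; AUC is computed on pooled scores (per-fold averaging is a
  plausible alternative reading of the original protocol).
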