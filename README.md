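# drspectra

Diffuse reflectance spectroscopy (DRS) measures the light a tissue sends
back after multiple scattering and absorption events, through a contact
fiber probe whose source-detector distance (SDD) controls how deep the
interrogated volume reaches. Broadband DRS (here 350–1919 nm across a
visible and a near-infrared spectrometer) carries the signatures of blood
volume and oxygenation in the visible range and of water, lipid and
collagen in the near-infrared, which is enough to separate tumor from
normal mucosa — the use case this package is built around is colorectal
cancer detection with a small (630 µm) and a large (2500 µm) SDD probe.

`drspectra` provides the full analysis chain as tested R code:

* **Preprocessing** — calibration
  `R(λ) = (I_tissue − I_bg) / (I_ref − I_bg)`, VIS/NIR stitching by a
  101-point cross-fade over the 1095–1130 nm overlap, min-max scaling of
  each wavelength to [−1, +1] on training rows only, and wavelength-range /
  discrete-wavelength selection.
* **Classification** — soft-margin kernel SVMs
  (`f(x) = Σ yᵢαᵢ K(x, xᵢ) + w₀`; linear/quadratic/cubic polynomial and
  fine/medium/coarse Gaussian kernels, C = 1) with its own SMO solver,
  evaluated by repeated stratified twofold cross-validation reporting
  sensitivity, specificity, accuracy and AUC as mean ± SD over 10
  iterations.
* **Probed depth** — MCML-style Monte Carlo photon transport in a
  semi-infinite medium (compiled code, 50 µm cylindrical bins, exact energy
  bookkeeping), photon-hitting-density maps
  `PHD(x, z) = Φ_src(|x − x_s|, z) · Φ_det(|x − x_d|, z)`, and probed depth
  as the z of the PHD maximum under the fiber midpoint, validated against an
  extrapolated-boundary diffusion dipole.
* **Synthetic data** — a chromophore-based generator (hemoglobins, water,
  lipid, collagen + scattering power law) with per-patient and per-site
  variability and a two-compartment depth-contrast mechanism, so the whole
  pipeline is testable without patient data.

## Worked example

```r
library(drspectra)

specs <- default_class_specs(n_patients = 14, sites_per_patient = 15)
g <- generate_dataset(specs$normal, specs$tumor, sdd_um = 630, seed = 42)
g$dataset
#> <spectra_dataset> 420 spectra x 1570 wavelengths (350.0-1919.0 nm), SDD 630 um
#>   labels: 210 normal (-1), 210 tumor (+1); scaling: raw

cv <- evaluate_cv(g$dataset, svm_config("poly2"), n_iterations = 10, seed = 1)
cv
#> <cv_result> 10 iterations (poly2 kernel): sens 85.5+-1.3% | spec 95.6+-1.9% | acc 90.5+-1.3% | AUC 0.974+-0.007

props <- optical_properties(specs$tumor$model, c(500, 1150, 1450))
depth_profile(props, sdd_um = 2500, n_photons = 1e5, seed = 1)
#>   wavelength depth_um
#> 1        500      475
#> 2       1150      925
#> 3       1450      675
```

Reading the output: the generator produced 420 site-level spectra (14
patients × 15 sites per class) at the small-SDD geometry; the quadratic SVM
separates the two synthetic classes with a cross-validated AUC of
0.974 ± 0.007 — the default world is calibrated to land near the mid-0.9s,
the performance scale typical of clinical broadband-DRS tumor
classification, with patient-level variability as the limiting factor. The
depth profile shows the large probe interrogating ~0.5–0.9 mm depending on
wavelength: deepest where tissue is most transparent (~1150 nm), shallower
in the green (blood absorption) and in the 1450 nm water band.

Higher-level drivers: `kernel_comparison()` (six standard kernels on one
dataset), `wavelength_range_experiment()` (twelve literature wavelength
ranges under the quadratic kernel), `run_pipeline()` (synthesis →
preprocessing → both experiments → depth profiles for both SDDs, with a
hash manifest), and a command-line front end in `inst/cli/drs.R`
(`synth | mcdepth | classify | run-all`).

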