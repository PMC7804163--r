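#' Define a chromophore tissue model
#'
#' Parameterizes synthetic tissue as a linear mix of chromophore absorption
#' bases plus a scattering power law
#' \eqn{\mu_s(\lambda) = a (\lambda/\lambda_{ref})^{-b}}.
#'
#' @param concentrations named numeric vector of nonnegative concentration /
#'   volume fractions; names must be a subset of [chromophore_names()]
#' @param scattering_amplitude `a`, scattering coefficient at the reference
#'   wavelength, 1/mm (> 0). Note this is the full \eqn{\mu_s}; the reduced
#'   coefficient is \eqn{\mu_s' = \mu_s (1 - g)}.
#' @param scattering_power `b`, dimensionless power-law exponent
#' @param reference_wavelength nm, must lie inside the simulated grid
#' @return object of class `chromophore_model`
#' @examples
#' chromophore_model(c(water = 0.65, lipid = 0.1), 12, 1.2)
#' @export
chromophore_model <- function(concentrations, scattering_amplitude,
                              scattering_power, reference_wavelength = 800) {
  conc <- structure(rep(0, 5), names = chromophore_names())
  if (length(concentrations)) {
    if (is.null(names(concentrations)) ||
        !all(names(concentrations) %in% chromophore_names()))
      stop("concentrations must be named with chromophore_names()")
    if (any(concentrations < 0)) stop("concentration fractions must be >= 0")
    conc[names(concentrations)] <- concentrations
  }
  if (conc[["water"]] + conc[["lipid"]] > 1)
    stop("water + lipid fractions exceed 1")
  if (scattering_amplitude <= 0) stop("scattering_amplitude must be > 0")
  structure(list(concentrations = conc,
                 scattering_amplitude = scattering_amplitude,
                 scattering_power = scattering_power,
                 reference_wavelength = reference_wavelength),
            class = "chromophore_model")
}

#' Per-wavelength optical properties from a chromophore model
#'
#' \eqn{\mu_a(\lambda) = \sum_c c_c \beta_c(\lambda)} over the absorption
#' basis, \eqn{\mu_s(\lambda) = a (\lambda/\lambda_{ref})^{-b}}; anisotropy
#' and refractive indices take the conventional soft-tissue values g = 0.9,
#' \eqn{\eta_{rel}} = 1.4, \eqn{\eta_{out}} = 1.
#'
#' @param model a [chromophore_model()]
#' @param wavelengths nm grid (within the supported basis range)
#' @param g,n_rel,n_out anisotropy factor and refractive indices
#' @return object of class `drs_props`: data frame with columns
#'   `wavelength`, `mua`, `mus` (1/mm) and attributes `g`, `n_rel`, `n_out`
#' @export
optical_properties <- function(model, wavelengths, g = 0.9, n_rel = 1.4,
                               n_out = 1.0) {
  stopifnot(inherits(model, "chromophore_model"))
  if (model$reference_wavelength < min(wavelengths) - 1e-9 ||
      model$reference_wavelength > max(wavelengths) + 1e-9)
    stop("reference_wavelength outside the simulated grid")
  B <- absorption_basis(wavelengths)
  mua <- as.numeric(B %*% model$concentrations)
  mus <- model$scattering_amplitude *
    (wavelengths / model$reference_wavelength)^(-model$scattering_power)
  if (any(mus <= 0)) stop("configuration yields nonpositive mu_s")
  out <- data.frame(wavelength = as.numeric(wavelengths), mua = mua, mus = mus)
  attr(out, "g") <- g
  attr(out, "n_rel") <- n_rel
  attr(out, "n_out") <- n_out
  class(out) <- c("drs_props", "data.frame")
  out
}

#' Forward diffuse reflectance of a tissue model at a probe geometry
#'
#' Diffusion-approximation stand-in for the measured DRS signal: evaluates the
#' extrapolated-boundary dipole reflectance ([diffusion_reflectance()]) at the
#' probe source-detector distance for every wavelength. When absorption
#' exceeds reduced scattering at some wavelengths (strong water bands) the
#' diffusion approximation is formally invalid there; a note is emitted and
#' values are still returned.
#'
#' @param props a `drs_props` table from [optical_properties()]
#' @param sdd_um source-detector distance, micrometres (> 0)
#' @param quiet suppress the diffusion-validity note
#' @return numeric reflectance spectrum (1/mm^2), strictly positive
#' @export
forward_reflectance <- function(props, sdd_um, quiet = FALSE) {
  stopifnot(inherits(props, "drs_props"), sdd_um > 0)
  g <- attr(props, "g")
  musp <- props$mus * (1 - g)
  n_bad <- sum(props$mua > musp)
  if (n_bad > 0 && !quiet)
    message("forward_reflectance: diffusion validity (mu_a <= mu_s') violated ",
            "at ", n_bad, " of ", nrow(props), " wavelengths; values returned")
  diffusion_reflectance(props$mua, musp, sdd_um / 1000,
                        n_rel = attr(props, "n_rel") / attr(props, "n_out"))
}

#' Define a synthetic tissue class
#'
#' Bundles the chromophore models and variance components used to simulate one
#' tissue class. Two-layer depth contrast is emulated by a superficial and a
#' deep chromophore model mixed with an SDD-dependent weight (see
#' [generate_dataset()]): large-SDD probes see proportionally more of the deep
#' model, mirroring how larger fiber separations interrogate deeper tissue.
#'
#' @param label class label: -1 (normal) or +1 (tumor)
#' @param model superficial [chromophore_model()]
#' @param model_deep deep-layer model; defaults to `model` (homogeneous tissue)
#' @param per_site_jitter_sd relative SD of per-site concentration jitter
#' @param per_patient_sd relative SD of the patient-level random effect
#' @param n_patients,sites_per_patient sampling structure (>= 1)
#' @return object of class `class_spec`
#' @export
class_spec <- function(label, model, model_deep = model,
                       per_site_jitter_sd = 0.05, per_patient_sd = 0.10,
                       n_patients = 14, sites_per_patient = 15) {
  stopifnot(label %in% c(-1, 1), inherits(model, "chromophore_model"),
            inherits(model_deep, "chromophore_model"),
            per_site_jitter_sd >= 0, per_patient_sd >= 0,
            n_patients >= 1, sites_per_patient >= 1)
  structure(list(label = as.integer(label), model = model,
                 model_deep = model_deep,
                 per_site_jitter_sd = per_site_jitter_sd,
                 per_patient_sd = per_patient_sd,
                 n_patients = as.integer(n_patients),
                 sites_per_patient = as.integer(sites_per_patient)),
            class = "class_spec")
}

# SDD-dependent weight of the deep model; 630 um -> 0.24, 2500 um -> 0.56
.deep_weight <- function(sdd_um) sdd_um / (sdd_um + 2000)

# mix two chromophore models with weight w on the second
.mix_models <- function(m1, m2, w) {
  chromophore_model(
    (1 - w) * m1$concentrations + w * m2$concentrations,
    (1 - w) * m1$scattering_amplitude + w * m2$scattering_amplitude,
    (1 - w) * m1$scattering_power + w * m2$scattering_power,
    m1$reference_wavelength)
}

# smooth positive lamp x detector response shared by tissue and reference
# channels (cancels exactly under calibration); tungsten-halogen-like shape
.lamp_response <- function(wavelengths) {
  1500 * exp(-((wavelengths - 1000) / 550)^2 / 2) + 200
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic two-class DRS dataset
#'
#' Simulates the full raw-measurement chain for every site of both classes:
#' patient-level and site-level relative jitter on chromophore concentrations
#' and scattering, forward diffusion reflectance at the probe SDD, a shared
#' lamp-times-detector response applied to tissue and reference channels on
#' the VIS and NIR spectrometer grids, a constant background level, and
#' multiplicative Gaussian intensity noise on the tissue channel. The raw
#' bundles are then run through [calibrate()] and [merge_vis_nir()] to produce
#' the calibrated, merged [spectra_dataset()].
#'
#' @param normal,tumor [class_spec()] objects with labels -1 and +1
#' @param sdd_um probe source-detector distance, micrometres
#' @param noise_sd relative SD of multiplicative tissue-intensity noise
#' @param seed integer seed; the run is bit-reproducible given the seed
#' @param vis_grid,nir_grid spectrometer wavelength grids, nm
#' @param out_grid unified grid for the merged dataset
#' @param background_level constant detector background, counts
#' @param keep_bundles also return the per-site raw three-channel bundles
#' @return list with elements `dataset` (a [spectra_dataset()]) and `bundles`
#'   (list of raw bundles, or `NULL` unless `keep_bundles`)
#' @export
generate_dataset <- function(normal, tumor, sdd_um, noise_sd = 0.03, seed,
                             vis_grid = seq(350, 1130, by = 1),
                             nir_grid = seq(1095, 1919, by = 1),
                             out_grid = seq(350, 1919, by = 1),
                             background_level = 120,
                             keep_bundles = FALSE) {
  stopifnot(inherits(normal, "class_spec"), inherits(tumor, "class_spec"),
            normal$label == -1L, tumor$label == 1L, noise_sd >= 0, sdd_um > 0)
  if (missing(seed)) stop("a seed is required")

  full_grid <- sort(unique(c(vis_grid, nir_grid)))
  w_deep <- .deep_weight(sdd_um)
  resp_vis <- .lamp_response(vis_grid)
  resp_nir <- .lamp_response(nir_grid)
  n_clamped <- 0L

  .with_seed(seed, {
    rows <- list(); labels <- integer(0); ids <- character(0)
    bundles <- if (keep_bundles) list() else NULL
    for (spec in list(normal, tumor)) {
      cls <- if (spec$label == 1L) "T" else "N"
      mixed <- .mix_models(spec$model, spec$model_deep, w_deep)
      for (p in seq_len(spec$n_patients)) {
        pat_fac <- 1 + rnorm(6, sd = spec$per_patient_sd)
        for (s in seq_len(spec$sites_per_patient)) {
          site_fac <- 1 + rnorm(6, sd = spec$per_site_jitter_sd)
          fac <- pat_fac * site_fac
          conc <- mixed$concentrations * fac[1:5]
          if (any(conc < 0)) {
            n_clamped <- n_clamped + sum(conc < 0)
            conc[conc < 0] <- 0
          }
          wl_sum <- conc[["water"]] + conc[["lipid"]]
          if (wl_sum > 0.98) {  # keep jittered volume fractions physical
            conc[c("water", "lipid")] <- conc[c("water", "lipid")] * 0.98 / wl_sum
            n_clamped <- n_clamped + 1L
          }
          a <- max(mixed$scattering_amplitude * fac[6], 1e-6)
          site_model <- chromophore_model(conc, a, mixed$scattering_power,
                                          mixed$reference_wavelength)
          props <- optical_properties(site_model, full_grid)
          refl <- forward_reflectance(props, sdd_um, quiet = TRUE)
          refl_vis <- refl[match(vis_grid, full_grid)]
          refl_nir <- refl[match(nir_grid, full_grid)]
          noise_vis <- if (noise_sd > 0)
            1 + rnorm(length(vis_grid), sd = noise_sd) else 1
          noise_nir <- if (noise_sd > 0)
            1 + rnorm(length(nir_grid), sd = noise_sd) else 1
          id <- sprintf("%s_p%02d_s%02d", cls, p, s)
          bundle <- structure(list(
            vis = list(wavelengths = vis_grid,
                       tissue = background_level + resp_vis * refl_vis * noise_vis,
                       reference = background_level + resp_vis,
                       background = rep(background_level, length(vis_grid))),
            nir = list(wavelengths = nir_grid,
                       tissue = background_level + resp_nir * refl_nir * noise_nir,
                       reference = background_level + resp_nir,
                       background = rep(background_level, length(nir_grid))),
            metadata = list(patient = sprintf("%s_p%02d", cls, p), site = id,
                            label = spec$label, sdd_um = sdd_um, seed = seed)),
            class = "raw_bundle")
          cal_vis <- calibrate(bundle$vis$tissue, bundle$vis$reference,
                               bundle$vis$background, vis_grid)
          cal_nir <- calibrate(bundle$nir$tissue, bundle$nir$reference,
                               bundle$nir$background, nir_grid)
          merged <- merge_vis_nir(cal_vis, cal_nir, out_grid = out_grid)
          rows[[id]] <- merged$reflectance
          labels <- c(labels, spec$label)
          ids <- c(ids, id)
          if (keep_bundles) bundles[[id]] <- bundle
        }
      }
    }
    if (n_clamped > 0)
      message("generate_dataset: clamped ", n_clamped,
              " negative jittered concentrations to 0")
    X <- do.call(rbind, rows)
    rownames(X) <- NULL
    list(dataset = spectra_dataset(X, labels, out_grid, sdd = sdd_um, ids = ids),
         bundles = bundles)
  })
}

#' Default two-class tissue parameterization
#'
#' Normal mucosa versus tumor chromophore models reflecting the angiogenesis
#' narrative of colorectal carcinogenesis: tumors carry more total hemoglobin
#' at lower oxygen saturation, more water, less lipid, and somewhat less
#' organized collagen, in both superficial (mucosal) and deep (submucosal)
#' compartments. `contrast` linearly scales the tumor-minus-normal parameter
#' difference (1 = default world; larger values give more separable classes).
#'
#' @param contrast nonnegative multiplier on the class parameter difference
#' @param n_patients,sites_per_patient sampling structure per class
#' @param per_site_jitter_sd,per_patient_sd variance components
#' @return list with elements `normal` and `tumor` ([class_spec()] objects)
#' @export
default_class_specs <- function(contrast = 1, n_patients = 14,
                                sites_per_patient = 15,
                                per_site_jitter_sd = 0.07,
                                per_patient_sd = 0.15) {
  # normal-mucosa baselines and tumor-minus-normal deltas, calibrated once so
  # that the contrast = 1 world yields quadratic-SVM CV AUC near the
  # mid-0.9s at the small SDD (see the methods vignette)
  normal_sup <- list(c(oxyhemoglobin = 0.0036, deoxyhemoglobin = 0.0012,
                       water = 0.65, lipid = 0.10, collagen = 0.15), 12, 1.2)
  delta_sup <- list(c(oxyhemoglobin = 0.00025, deoxyhemoglobin = 0.00035,
                      water = 0.021, lipid = -0.008, collagen = -0.008),
                    0.42, -0.04)
  normal_deep <- list(c(oxyhemoglobin = 0.0040, deoxyhemoglobin = 0.0015,
                        water = 0.60, lipid = 0.15, collagen = 0.25), 13, 1.1)
  delta_deep <- list(c(oxyhemoglobin = 0.00035, deoxyhemoglobin = 0.00045,
                       water = 0.050, lipid = -0.021, collagen = -0.021),
                     0.6, -0.06)
  shift <- function(base, delta) {
    conc <- pmax(base[[1]] + contrast * delta[[1]], 0)
    wl_sum <- conc[["water"]] + conc[["lipid"]]
    if (wl_sum > 0.98)  # keep volume fractions physical at extreme contrast
      conc[c("water", "lipid")] <- conc[c("water", "lipid")] * 0.98 / wl_sum
    chromophore_model(conc,
                      base[[2]] + contrast * delta[[2]],
                      base[[3]] + contrast * delta[[3]])
  }
  mk <- function(label, sup, deep)
    class_spec(label, sup, deep, per_site_jitter_sd, per_patient_sd,
               n_patients, sites_per_patient)
  list(normal = mk(-1, chromophore_model(normal_sup[[1]], normal_sup[[2]],
                                         normal_sup[[3]]),
                   chromophore_model(normal_deep[[1]], normal_deep[[2]],
                                     normal_deep[[3]])),
       tumor = mk(1, shift(normal_sup, delta_sup),
                  shift(normal_deep, delta_deep)))
}

#' Deep-contrast tissue parameterization
#'
#' Both classes share the normal superficial (mucosal) model; only the deep
#' (submucosal) models differ. Because the deep model's mixing weight grows
#' with SDD, a larger source-detector distance sees more of the class
#' contrast: the configuration used to demonstrate that large-SDD probes
#' classify better when the diagnostic contrast lies deep.
#'
#' @inheritParams default_class_specs
#' @return list with elements `normal` and `tumor`
#' @export
deep_contrast_specs <- function(contrast = 1, n_patients = 14,
                                sites_per_patient = 15,
                                per_site_jitter_sd = 0.07,
                                per_patient_sd = 0.15) {
  specs <- default_class_specs(contrast, n_patients, sites_per_patient,
                               per_site_jitter_sd, per_patient_sd)
  shared_sup <- specs$normal$model
  list(normal = class_spec(-1, shared_sup, specs$normal$model_deep,
                           per_site_jitter_sd, per_patient_sd,
                           n_patients, sites_per_patient),
       tumor = class_spec(1, shared_sup, specs$tumor$model_deep,
                          per_site_jitter_sd, per_patient_sd,
                          n_patients, sites_per_patient))
}
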