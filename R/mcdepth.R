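#' Optical properties of a homogeneous medium at one wavelength
#'
#' @param mua absorption coefficient, 1/mm (>= 0)
#' @param mus scattering coefficient, 1/mm (> 0)
#' @param g scattering anisotropy factor, -1 < g < 1 (default 0.9)
#' @param n_rel tissue refractive index (default 1.4)
#' @param n_out outer-medium refractive index (default 1.0)
#' @return object of class `optical_props`
#' @export
optical_props <- function(mua, mus, g = 0.9, n_rel = 1.4, n_out = 1.0) {
  stopifnot(mua >= 0, mus > 0, g > -1, g < 1, n_rel >= 1, n_out >= 1)
  structure(list(mua = mua, mus = mus, g = g, n_rel = n_rel, n_out = n_out),
            class = "optical_props")
}

#' Monte Carlo fluence simulation in a semi-infinite medium
#'
#' Standard photon-packet random walk (MCML scheme) specialized to a single
#' semi-infinite homogeneous layer under a pencil beam: specular deduction
#' \eqn{((\eta_{rel}-\eta_{out})/(\eta_{rel}+\eta_{out}))^2} at launch,
#' exponential step lengths \eqn{-\ln\xi/(\mu_a+\mu_s)}, weight drop
#' \eqn{\mu_a/(\mu_a+\mu_s)} scored into cylindrical (r, z) bins,
#' Henyey-Greenstein direction sampling, unpolarized Fresnel internal
#' reflection (with total internal reflection) at the top boundary, and
#' Russian roulette below a weight threshold. Fluence is absorbed weight per
#' bin divided by (bin volume x mu_a x photons launched). Escaping weight is
#' also scored radially, giving the radially resolved diffuse reflectance.
#'
#' Energy bookkeeping is exact by construction: the roulette entry records
#' the net weight change (killed minus injected into survivors), so
#' specular + diffuse + absorbed (in + beyond grid) + roulette_net + lost
#' equals 1 to floating-point rounding. `lost` is weight abandoned at the
#' step cap, relevant only for (near-)zero absorption.
#'
#' @param props an [optical_props()] object
#' @param n_photons photon packets to launch (>= 1000)
#' @param seed integer seed (mandatory; self-contained RNG, does not touch
#'   R's RNG state)
#' @param dr,dz radial and depth bin size, mm (default 0.05 = 50 um)
#' @param r_extent,z_extent grid extent, mm (default 5 x 5 mm)
#' @param w_threshold,roulette_p Russian roulette weight threshold and
#'   survival probability
#' @param max_steps per-photon step cap
#' @return object of class `fluence_map`: fluence matrix (`NULL` when
#'   `mua = 0`), absorbed-weight matrix, radially resolved diffuse
#'   reflectance `rd` (1/mm^2), bin centers, and the `bookkeeping` ledger
#' @export
simulate_fluence <- function(props, n_photons = 1e5, seed,
                             dr = 0.05, dz = 0.05,
                             r_extent = 5, z_extent = 5,
                             w_threshold = 1e-4, roulette_p = 0.1,
                             max_steps = 1e7) {
  stopifnot(inherits(props, "optical_props"), n_photons >= 1000)
  if (missing(seed)) stop("a seed is required")
  nr <- as.integer(round(r_extent / dr))
  nz <- as.integer(round(z_extent / dz))
  res <- .mc_simulate_cpp(props$mua, props$mus, props$g, props$n_rel,
                          props$n_out, as.integer(n_photons), dr, dz, nr, nz,
                          as.numeric(seed), w_threshold, roulette_p, max_steps)
  r_centers <- (seq_len(nr) - 0.5) * dr
  z_centers <- (seq_len(nz) - 0.5) * dz
  ring_vol <- 2 * pi * r_centers * dr * dz       # annular bin volumes, mm^3
  ring_area <- 2 * pi * r_centers * dr           # annular exit areas, mm^2
  fluence <- if (props$mua > 0)
    res$absorbed / (props$mua * outer(ring_vol, rep(1, nz)) * n_photons)
  else NULL
  bk <- list(specular_reflected = res$specular,
             diffuse_reflected = res$diffuse,
             absorbed_in_grid = res$absorbed_in_grid,
             absorbed_beyond_grid = res$absorbed_beyond_grid,
             roulette_net = res$roulette_net,
             lost = res$lost)
  structure(list(fluence = fluence, absorbed = res$absorbed,
                 rd = res$rd_weight / (ring_area * n_photons),
                 diffuse_beyond_grid = res$diffuse_beyond_grid,
                 r_centers = r_centers, z_centers = z_centers,
                 dr = dr, dz = dz, n_photons = n_photons,
                 bookkeeping = bk, props = props, seed = seed),
            class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  bk <- x$bookkeeping
  cat(sprintf(
    "<fluence_map> %dx%d bins of %.0f um, %g photons (mua=%g, mus=%g, g=%g)\n",
    length(x$r_centers), length(x$z_centers), x$dr * 1000, x$n_photons,
    x$props$mua, x$props$mus, x$props$g))
  cat(sprintf("  specular %.4f | diffuse %.4f | absorbed %.4f (+%.4f beyond)\n",
              bk$specular_reflected, bk$diffuse_reflected,
              bk$absorbed_in_grid, bk$absorbed_beyond_grid))
  invisible(x)
}

# total of the energy ledger; 1 up to floating-point rounding
energy_closure <- function(fmap) {
  bk <- fmap$bookkeeping
  bk$specular_reflected + bk$diffuse_reflected + bk$absorbed_in_grid +
    bk$absorbed_beyond_grid + bk$roulette_net + bk$lost
}

# interpolate a cylindrical fluence map at radius r (vectorized over r),
# returning a matrix length(r) x nz; constant inside the first bin center,
# zero beyond the grid edge
.fluence_at_radius <- function(fmap, r) {
  F <- if (is.null(fmap$fluence)) fmap$absorbed else fmap$fluence
  rc <- fmap$r_centers
  nr <- length(rc)
  out <- matrix(0, length(r), ncol(F))
  for (k in seq_along(r)) {
    if (r[k] > rc[nr]) next
    if (r[k] <= rc[1]) { out[k, ] <- F[1, ]; next }
    i <- findInterval(r[k], rc)
    w <- (r[k] - rc[i]) / (rc[i + 1] - rc[i])
    out[k, ] <- (1 - w) * F[i, ] + w * F[i + 1, ]
  }
  out
}

#' Photon hitting density map for a source-detector fiber pair
#'
#' Converts the cylindrically symmetric source and detector fluence maps to
#' the Cartesian x-z plane through both fibers and multiplies them:
#' \eqn{PHD(x, z) = \Phi_{src}(|x - x_{src}|, z)\,\Phi_{det}(|x - x_{det}|, z)}.
#' By reciprocity the detector fluence map of an identical fiber is the same
#' simulation as the source map. Radial values are linearly interpolated
#' between cylindrical bin centers; nodes whose radius falls beyond the
#' cylindrical grid contribute zero. The x axis is centered on the fiber
#' midpoint.
#'
#' @param src_fluence,det_fluence `fluence_map` objects on the same grid
#' @param src_x,det_x fiber positions along x, micrometres
#' @param x_extent Cartesian map width, mm (default 3.75)
#' @return object of class `phd_map`: `values` (nx x nz), `x_centers`
#'   and `z_centers` (mm), `src_x`, `det_x` (um)
#' @export
compute_phd <- function(src_fluence, det_fluence, src_x, det_x,
                        x_extent = 3.75) {
  stopifnot(inherits(src_fluence, "fluence_map"),
            inherits(det_fluence, "fluence_map"))
  if (src_fluence$dr != det_fluence$dr || src_fluence$dz != det_fluence$dz)
    stop("source and detector maps must share grid resolution")
  if (abs(det_x - src_x) / 1000 > x_extent)
    stop("fiber separation exceeds the x extent of the PHD map")
  dx <- src_fluence$dr
  nx <- as.integer(round(x_extent / dx))
  if (nx %% 2L == 0L) nx <- nx + 1L  # odd count => a bin center at the midpoint
  mid <- (src_x + det_x) / 2 / 1000  # mm
  x_centers <- mid + (seq_len(nx) - (nx + 1) / 2) * dx
  phi_s <- .fluence_at_radius(src_fluence, abs(x_centers - src_x / 1000))
  phi_d <- .fluence_at_radius(det_fluence, abs(x_centers - det_x / 1000))
  structure(list(values = phi_s * phi_d, x_centers = x_centers,
                 z_centers = src_fluence$z_centers,
                 src_x = src_x, det_x = det_x),
            class = "phd_map")
}

#' Probed depth from a photon hitting density map
#'
#' The depth of the maximum PHD value in the grid column nearest to the
#' source-detector midpoint, reported at the bin center; ties break to the
#' smallest depth.
#'
#' @param phd a `phd_map`
#' @return depth in micrometres
#' @export
probed_depth <- function(phd) {
  stopifnot(inherits(phd, "phd_map"))
  mid <- (phd$src_x + phd$det_x) / 2 / 1000
  col <- which.min(abs(phd$x_centers - mid))
  v <- phd$values[col, ]
  if (all(v == 0)) stop("all-zero PHD in the midpoint column")
  phd$z_centers[which.max(v)] * 1000  # which.max takes the first (smallest z)
}

#' Probed-depth profile across wavelengths
#'
#' For each wavelength: simulate the fluence map at the tabulated optical
#' properties, reuse it as both source and detector map (reciprocity,
#' identical fibers placed at -SDD/2 and +SDD/2), build the PHD map, and
#' extract the probed depth.
#'
#' @param props_by_wavelength a `drs_props` table ([optical_properties()]) or
#'   data frame with columns `wavelength`, `mua`, `mus`
#' @param sdd_um source-detector distance, micrometres
#' @param n_photons photons per wavelength
#' @param seed master seed; one sub-seed is derived per wavelength
#' @param g,n_rel,n_out medium constants used when `props_by_wavelength` lacks
#'   attributes
#' @param ... passed to [simulate_fluence()]
#' @return object of class `depth_profile`: data frame with columns
#'   `wavelength` and `depth_um`, with attributes `sdd_um`, `depth_range`
#' @export
depth_profile <- function(props_by_wavelength, sdd_um, n_photons = 1e5, seed,
                          g = 0.9, n_rel = 1.4, n_out = 1.0, ...) {
  if (missing(seed)) stop("a seed is required")
  pw <- as.data.frame(props_by_wavelength)
  stopifnot(all(c("wavelength", "mua", "mus") %in% names(pw)))
  if (!is.null(attr(props_by_wavelength, "g"))) {
    g <- attr(props_by_wavelength, "g")
    n_rel <- attr(props_by_wavelength, "n_rel")
    n_out <- attr(props_by_wavelength, "n_out")
  }
  depths <- vapply(seq_len(nrow(pw)), function(i) {
    op <- optical_props(pw$mua[i], pw$mus[i], g = g, n_rel = n_rel,
                        n_out = n_out)
    fm <- simulate_fluence(op, n_photons = n_photons,
                           seed = derive_seed(seed, paste0("wl", pw$wavelength[i])),
                           ...)
    phd <- compute_phd(fm, fm, -sdd_um / 2, sdd_um / 2)
    probed_depth(phd)
  }, numeric(1))
  out <- data.frame(wavelength = pw$wavelength, depth_um = depths)
  attr(out, "sdd_um") <- sdd_um
  attr(out, "depth_range") <- range(depths)
  class(out) <- c("depth_profile", "data.frame")
  out
}
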