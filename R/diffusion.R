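#' Diffusion-theory radially resolved diffuse reflectance
#'
#' Steady-state reflectance of a semi-infinite homogeneous turbid medium under
#' a pencil beam, in the extrapolated-boundary dipole approximation: an
#' isotropic point source is placed one transport mean free path
#' \eqn{z_0 = 1/(\mu_a + \mu_s')} below the surface and its negative image at
#' \eqn{-(z_0 + 2 z_b)}, with \eqn{z_b = 2 A D} set by the internal-reflection
#' parameter \eqn{A} of the refractive-index mismatch. Valid when scattering
#' dominates absorption (\eqn{\mu_s' \gg \mu_a}) and at source-detector
#' distances of at least a few transport mean free paths.
#'
#' @param mua absorption coefficient, 1/mm
#' @param musp reduced scattering coefficient \eqn{\mu_s' = \mu_s (1 - g)}, 1/mm
#' @param rho radial source-detector distance on the surface, mm
#' @param n_rel relative refractive index tissue/outside (default 1.4)
#' @return diffuse reflectance per unit area (1/mm^2), same length as the
#'   longest of the vectorized arguments
#' @examples
#' diffusion_reflectance(0.01, 1, 2.5)
#' @export
diffusion_reflectance <- function(mua, musp, rho, n_rel = 1.4) {
  stopifnot(all(mua >= 0), all(musp > 0), all(rho > 0), n_rel >= 1)
  mutp <- mua + musp
  z0 <- 1 / mutp
  D <- 1 / (3 * mutp)
  mueff <- sqrt(3 * mua * mutp)
  A <- .internal_reflection_A(n_rel)
  zb <- 2 * A * D
  zp <- z0 + 2 * zb
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt(zp^2 + rho^2)
  (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
    zp * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) / (4 * pi)
}

# Groenhuis/Egan-Hilgeman polynomial for the internal reflection parameter
# A = (1 + r_d)/(1 - r_d); exact enough for n_rel in [1, 1.6]
.internal_reflection_A <- function(n_rel) {
  if (n_rel == 1) return(1)
  rd <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  (1 + rd) / (1 - rd)
}
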