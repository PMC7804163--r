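#' Synthetic chromophore absorption basis
#'
#' Deterministic per-chromophore absorption spectra (1/mm per unit
#' concentration fraction) for the five chromophores that dominate soft-tissue
#' absorption between 350 and 1919 nm. The bases are sums of Gaussian bands
#' plus smooth baselines placed at the canonical band positions: hemoglobin
#' Soret/Q bands near 420/540/580 nm, deoxyhemoglobin near 430/555/760 nm,
#' water overtone bands near 970/1200/1450/1940 nm, lipid bands near
#' 930/1210/1730 nm, and a monotonically decreasing collagen/baseline term.
#' Band positions and rough magnitudes follow the tissue-optics literature;
#' the exact numeric shapes are a generator choice, not measured extinction
#' tables.
#'
#' @param wavelengths numeric vector, nm, strictly increasing, within
#'   \[350, 1919\]
#' @return numeric matrix, `length(wavelengths)` x 5, columns
#'   `oxyhemoglobin`, `deoxyhemoglobin`, `water`, `lipid`, `collagen`;
#'   all values nonnegative
#' @examples
#' B <- absorption_basis(seq(350, 1919, by = 10))
#' @export
absorption_basis <- function(wavelengths) {
  wl <- as.numeric(wavelengths)
  if (length(wl) > 1 && any(diff(wl) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(wl < 350 - 1e-9) || any(wl > 1919 + 1e-9))
    stop("wavelength grid outside supported range [350, 1919] nm; got [",
         min(wl), ", ", max(wl), "]")

  g <- function(center, amp, width) amp * exp(-((wl - center) / width)^2 / 2)

  oxy <- g(420, 300, 18) + g(542, 35, 15) + g(577, 40, 12) +
    g(920, 1.2, 90) + 0.4
  deoxy <- g(430, 350, 20) + g(555, 45, 18) + g(760, 4, 35) + 0.4
  water <- g(970, 0.045, 35) + g(1200, 0.10, 45) + g(1450, 2.9, 60) +
    g(1940, 12, 70)
  lipid <- g(930, 0.11, 25) + g(1210, 0.55, 40) + g(1400, 0.20, 60) +
    g(1730, 1.1, 50)
  collagen <- 2.0 * exp(-(wl - 350) / 300) + 0.01

  out <- cbind(oxyhemoglobin = oxy, deoxyhemoglobin = deoxy, water = water,
               lipid = lipid, collagen = collagen)
  rownames(out) <- NULL
  out
}

#' Chromophore names supported by the synthetic basis
#' @return character vector of the five basis column names
#' @export
chromophore_names <- function() {
  c("oxyhemoglobin", "deoxyhemoglobin", "water", "lipid", "collagen")
}
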