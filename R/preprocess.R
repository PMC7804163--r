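#' Calibrate a raw tissue spectrum against reference and background
#'
#' Background subtraction followed by division by the background-subtracted
#' reference channel:
#' \deqn{R(\lambda) = \frac{I_{tissue}(\lambda) - I_{background}(\lambda)}
#'                         {I_{reference}(\lambda) - I_{background}(\lambda)}}
#' No clipping is applied; the ratio is returned as-is.
#'
#' @param tissue,reference,background intensity spectra on one common grid
#' @param wavelengths the common wavelength grid, nm
#' @param channel optional channel tag ("VIS"/"NIR"), carried as metadata
#' @return object of class `calibrated_spectrum`: list with `wavelengths`,
#'   `reflectance`, `channel`
#' @examples
#' calibrate(c(250, 250), c(450, 450), c(50, 50), c(500, 501))
#' @export
calibrate <- function(tissue, reference, background, wavelengths,
                      channel = NA_character_) {
  n <- length(wavelengths)
  if (length(tissue) != n || length(reference) != n || length(background) != n)
    stop("tissue/reference/background must share one wavelength grid")
  denom <- reference - background
  bad <- which(denom <= 0)
  if (length(bad))
    stop("calibration error: reference - background <= 0 at ",
         length(bad), " wavelength(s), first at ", wavelengths[bad[1]], " nm")
  structure(list(wavelengths = as.numeric(wavelengths),
                 reflectance = (tissue - background) / denom,
                 channel = channel),
            class = "calibrated_spectrum")
}

#' Merge VIS and NIR calibrated spectra across their overlap
#'
#' Below the overlap the merged spectrum equals the VIS channel, above it the
#' NIR channel. Inside the overlap both channels are linearly interpolated
#' onto 101 evenly spaced points indexed \eqn{i = 0..100} and cross-faded as
#' \deqn{R_i = \frac{(100 - i)\, R_{VIS,i} + i\, R_{NIR,i}}{100}}
#' so that each spectrometer dominates where it is most sensitive, then
#' re-interpolated onto the unified output grid. The result is continuous at
#' both overlap edges.
#'
#' @param vis,nir `calibrated_spectrum` objects whose grids both cover the
#'   overlap interval
#' @param overlap two-element numeric, nm (default `c(1095, 1130)`)
#' @param out_grid unified output grid, nm (default 1 nm steps over the union
#'   of both channel ranges)
#' @return object of class `merged_spectrum`: list with `wavelengths`,
#'   `reflectance`
#' @export
merge_vis_nir <- function(vis, nir, overlap = c(1095, 1130), out_grid = NULL) {
  stopifnot(inherits(vis, "calibrated_spectrum"),
            inherits(nir, "calibrated_spectrum"), length(overlap) == 2,
            overlap[1] < overlap[2])
  if (min(vis$wavelengths) > overlap[1] || max(vis$wavelengths) < overlap[2] ||
      min(nir$wavelengths) > overlap[1] || max(nir$wavelengths) < overlap[2])
    stop("merge error: both channels must cover the overlap [",
         overlap[1], ", ", overlap[2], "] nm")
  if (is.null(out_grid))
    out_grid <- seq(ceiling(min(vis$wavelengths)),
                    floor(max(nir$wavelengths)), by = 1)

  # The cross-fade weight index i runs 0..100 across the overlap; evaluating
  # the fade directly at the output wavelengths (continuous i) agrees exactly
  # with the 101-point formulation at each of the 101 points and avoids the
  # O(h^2) error of resampling through the intermediate grid, which keeps the
  # calibrate->merge round-trip exact on noiseless data.
  lo <- out_grid < overlap[1]
  hi <- out_grid > overlap[2]
  mid <- !lo & !hi
  refl <- numeric(length(out_grid))
  refl[lo] <- approx(vis$wavelengths, vis$reflectance, xout = out_grid[lo])$y
  refl[hi] <- approx(nir$wavelengths, nir$reflectance, xout = out_grid[hi])$y
  if (any(mid)) {
    lam <- out_grid[mid]
    vis_m <- approx(vis$wavelengths, vis$reflectance, xout = lam)$y
    nir_m <- approx(nir$wavelengths, nir$reflectance, xout = lam)$y
    i_frac <- 100 * (lam - overlap[1]) / diff(overlap)
    refl[mid] <- ((100 - i_frac) * vis_m + i_frac * nir_m) / 100
  }
  if (anyNA(refl))
    stop("merge error: output grid extends beyond the channel grids")
  structure(list(wavelengths = as.numeric(out_grid), reflectance = refl),
            class = "merged_spectrum")
}

#' Min-max scale dataset features to \[-1, +1\]
#'
#' Centers and scales each wavelength feature to span exactly \[-1, +1\] on
#' the fitting rows: offset = (max + min)/2 and half-range = (max - min)/2 are
#' computed on `fit_rows` only and applied to all rows, so that held-out rows
#' can legitimately fall outside \[-1, +1\] (no clipping). Constant features
#' map to 0. The per-feature parameters are stored in the returned dataset's
#' `scaling` field for reuse.
#'
#' @param dataset a [spectra_dataset()]
#' @param fit_rows indices of the rows (training set) the scaling statistics
#'   are computed on; defaults to all rows
#' @return the scaled `spectra_dataset`
#' @export
scale_features <- function(dataset, fit_rows = seq_len(nrow(dataset$X))) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  if (length(fit_rows) == 0) stop("fit_rows must be nonempty")
  Xf <- dataset$X[fit_rows, , drop = FALSE]
  mx <- apply(Xf, 2, max)
  mn <- apply(Xf, 2, min)
  offset <- (mx + mn) / 2
  half <- (mx - mn) / 2
  X <- sweep(dataset$X, 2, offset, "-")
  nz <- half > 0
  X[, nz] <- sweep(X[, nz, drop = FALSE], 2, half[nz], "/")
  X[, !nz] <- 0
  spectra_dataset(X, dataset$y, dataset$wavelengths, sdd = dataset$sdd,
                  ids = dataset$ids,
                  scaling = list(offset = offset, half_range = half,
                                 fit_rows = fit_rows))
}

# apply a previously fitted scaling state to a raw matrix
.apply_scaling <- function(X, scaling) {
  X <- sweep(X, 2, scaling$offset, "-")
  nz <- scaling$half_range > 0
  X[, nz] <- sweep(X[, nz, drop = FALSE], 2, scaling$half_range[nz], "/")
  X[, !nz] <- 0
  X
}

#' Subset dataset columns by wavelength ranges and discrete wavelengths
#'
#' Keeps every column whose wavelength lies in one of the closed intervals,
#' plus, for each discrete value, the single nearest grid column (ties break
#' to the lower wavelength). Column order is preserved and duplicates removed.
#'
#' @param dataset a [spectra_dataset()]
#' @param ranges list of 2-element numeric vectors `c(lo, hi)` in nm; may be
#'   a single vector for one range
#' @param values numeric vector of discrete wavelengths, nm
#' @return the column-subset `spectra_dataset`
#' @examples
#' \dontrun{subset_wavelengths(ds, ranges = list(c(400, 440), c(540, 580)))}
#' @export
subset_wavelengths <- function(dataset, ranges = NULL, values = NULL) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  wl <- dataset$wavelengths
  if (!is.null(ranges) && is.numeric(ranges)) ranges <- list(ranges)
  keep <- logical(length(wl))
  for (rg in ranges) {
    if (length(rg) != 2 || rg[1] > rg[2]) stop("each range must be c(lo, hi)")
    keep <- keep | (wl >= rg[1] & wl <= rg[2])
  }
  for (v in values) {
    d <- abs(wl - v)
    keep[which(d == min(d))[1]] <- TRUE  # which() returns the lowest index
  }
  if (!any(keep))
    stop("empty wavelength selection for ranges ",
         paste(vapply(ranges, function(r) paste(r, collapse = "-"),
                      character(1)), collapse = ", "),
         if (length(values)) paste(" and values", paste(values, collapse = ", ")))
  idx <- which(keep)
  sc <- dataset$scaling
  if (!is.null(sc)) {
    sc$offset <- sc$offset[idx]
    sc$half_range <- sc$half_range[idx]
  }
  spectra_dataset(dataset$X[, idx, drop = FALSE], dataset$y, wl[idx],
                  sdd = dataset$sdd, ids = dataset$ids, scaling = sc)
}
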