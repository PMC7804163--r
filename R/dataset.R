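#' Construct a spectra dataset
#'
#' The classifier-facing container: an n x m matrix of reflectance values with
#' one row per measured site and one column per wavelength, class labels in
#' \{-1, +1\} (normal mucosa = -1, tumor = +1), and the probe source-detector
#' distance the spectra were acquired with.
#'
#' @param X numeric matrix, n samples x m wavelengths
#' @param y integer labels, -1 or +1, length n
#' @param wavelengths numeric vector of length m, nm, strictly increasing
#' @param sdd source-detector distance in micrometres (metadata)
#' @param ids optional character vector of stable sample identifiers; used to
#'   key cross-validation splits so results do not depend on row order
#' @param scaling either `NULL` (raw) or the scaling state produced by
#'   [scale_features()]
#' @return an object of class `spectra_dataset`
#' @export
spectra_dataset <- function(X, y, wavelengths, sdd = NA_real_, ids = NULL,
                            scaling = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y))
    stop("rows of X (", nrow(X), ") != length of y (", length(y), ")")
  if (ncol(X) != length(wavelengths))
    stop("cols of X (", ncol(X), ") != length of wavelengths (",
         length(wavelengths), ")")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (is.null(ids)) ids <- sprintf("s%05d", seq_len(nrow(X)))
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  structure(list(X = X, y = as.integer(y), wavelengths = as.numeric(wavelengths),
                 sdd = sdd, ids = as.character(ids), scaling = scaling),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectra_dataset> %d spectra x %d wavelengths (%.1f-%.1f nm), SDD %s um\n",
    nrow(x$X), ncol(x$X), min(x$wavelengths), max(x$wavelengths),
    format(x$sdd)))
  cat(sprintf("  labels: %d normal (-1), %d tumor (+1); scaling: %s\n",
              sum(x$y == -1), sum(x$y == 1),
              if (is.null(x$scaling)) "raw" else "scaled [-1, +1]"))
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$X)

# row subset keeping all metadata consistent
.dataset_rows <- function(ds, idx) {
  spectra_dataset(ds$X[idx, , drop = FALSE], ds$y[idx], ds$wavelengths,
                  sdd = ds$sdd, ids = ds$ids[idx], scaling = ds$scaling)
}
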