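#' Write / read a raw spectrum bundle
#'
#' One CSV per spectrometer channel with columns `wavelength_nm`, `tissue`,
#' `reference`, `background`, plus a JSON sidecar carrying patient, site,
#' label, SDD and seed. Dialect: UTF-8, '.' decimal, comma separator.
#'
#' @param bundle a `raw_bundle` (see [generate_dataset()])
#' @param dir output directory (created if needed)
#' @param name file stem; defaults to the bundle's site id
#' @return invisibly, the paths written
#' @export
write_spectra <- function(bundle, dir, name = bundle$metadata$site) {
  stopifnot(inherits(bundle, "raw_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ch in c("vis", "nir")) {
    p <- file.path(dir, sprintf("%s_%s.csv", name, ch))
    data.table::fwrite(data.table::data.table(
      wavelength_nm = bundle[[ch]]$wavelengths,
      tissue = bundle[[ch]]$tissue,
      reference = bundle[[ch]]$reference,
      background = bundle[[ch]]$background), p)
    paths <- c(paths, p)
  }
  meta_path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(bundle$metadata, meta_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, meta_path))
}

#' @rdname write_spectra
#' @param name file stem used when writing
#' @export
read_spectra <- function(dir, name) {
  channels <- lapply(c(vis = "vis", nir = "nir"), function(ch) {
    p <- file.path(dir, sprintf("%s_%s.csv", name, ch))
    dt <- .read_checked_csv(p, c("wavelength_nm", "tissue", "reference",
                                 "background"))
    list(wavelengths = dt$wavelength_nm, tissue = dt$tissue,
         reference = dt$reference, background = dt$background)
  })
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  structure(c(channels, list(metadata = meta)), class = "raw_bundle")
}

.read_checked_csv <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path)
  missing_cols <- setdiff(required_cols, names(dt))
  if (length(missing_cols))
    stop("format error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (cl in required_cols) {
    bad <- which(!is.finite(dt[[cl]]))
    if (length(bad))
      stop("format error in ", path, ": non-finite '", cl,
           "' at data line ", bad[1])
  }
  wl <- dt[[required_cols[1]]]
  if (length(wl) > 1) {
    bad <- which(diff(wl) <= 0)
    if (length(bad))
      stop("format error in ", path, ": non-monotone wavelength grid at data line ",
           bad[1] + 1)
  }
  dt
}

#' Write / read a spectra dataset
#'
#' CSV matrix layout: first column `label` (-1/+1), remaining columns named
#' by wavelength in nm. Values round-trip at full float precision.
#'
#' @param dataset a [spectra_dataset()]
#' @param path CSV file path
#' @return `write_dataset` invisibly returns `path`; `read_dataset` returns a
#'   [spectra_dataset()] (sample ids are regenerated; scaling state is not
#'   serialized)
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  dt <- data.table::data.table(label = dataset$y)
  X <- dataset$X
  colnames(X) <- as.character(dataset$wavelengths)
  data.table::fwrite(cbind(dt, data.table::as.data.table(X)), path)
  invisible(path)
}

#' @rdname write_dataset
#' @param sdd source-detector distance tag to attach on read, um
#' @export
read_dataset <- function(path, sdd = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path)
  if (names(dt)[1] != "label")
    stop("format error in ", path, ": first column must be 'label'")
  wl <- suppressWarnings(as.numeric(names(dt)[-1]))
  if (anyNA(wl))
    stop("format error in ", path, ": non-numeric wavelength column name '",
         names(dt)[-1][which(is.na(wl))[1]], "'")
  if (length(wl) > 1 && any(diff(wl) <= 0))
    stop("format error in ", path, ": non-monotone wavelength grid at column ",
         which(diff(wl) <= 0)[1] + 1)
  X <- as.matrix(dt[, -1])
  if (any(!is.finite(X))) {
    bad <- which(rowSums(!is.finite(X)) > 0)[1]
    stop("format error in ", path, ": non-finite value at data line ", bad)
  }
  dimnames(X) <- NULL
  spectra_dataset(X, dt$label, wl, sdd = sdd)
}

#' Write / read an optical-property table
#'
#' CSV with columns `wavelength_nm`, `mu_a_per_mm`, `mu_s_per_mm`.
#'
#' @param props a `drs_props` table or data frame with columns `wavelength`,
#'   `mua`, `mus`
#' @param path CSV file path
#' @return `read_props` returns a data frame with columns `wavelength`,
#'   `mua`, `mus` (g/n attributes defaulted to 0.9/1.4/1.0)
#' @export
write_props <- function(props, path) {
  pw <- as.data.frame(props)
  data.table::fwrite(data.table::data.table(
    wavelength_nm = pw$wavelength, mu_a_per_mm = pw$mua,
    mu_s_per_mm = pw$mus), path)
  invisible(path)
}

#' @rdname write_props
#' @export
read_props <- function(path) {
  dt <- .read_checked_csv(path, c("wavelength_nm", "mu_a_per_mm",
                                  "mu_s_per_mm"))
  out <- data.frame(wavelength = dt$wavelength_nm, mua = dt$mu_a_per_mm,
                    mus = dt$mu_s_per_mm)
  attr(out, "g") <- 0.9
  attr(out, "n_rel") <- 1.4
  attr(out, "n_out") <- 1.0
  class(out) <- c("drs_props", "data.frame")
  out
}
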