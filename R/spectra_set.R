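#' Construct a spectra set
#'
#' A `spectra_set` bundles a wavelength grid with a matrix of absorbance
#' scans, one row per scan, plus a sample label for each scan. It is the
#' common currency of the pretreatment and calibration functions.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing and (within tolerance) evenly spaced.
#' @param absorbance Numeric matrix, scans in rows; `ncol` must equal
#'   `length(wavelengths)`.
#' @param sample_ids Character vector of per-scan labels, recycled from a
#'   single value if needed. Defaults to `"scan_1" ... "scan_n"`.
#'
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavelengths, absorbance, sample_ids = NULL) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (length(wavelengths) < 2L) {
    stop("a spectra_set needs at least two wavelengths", call. = FALSE)
  }
  dw <- diff(wavelengths)
  if (any(dw <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (diff(range(dw)) > 1e-6 * mean(dw)) {
    stop("wavelength grid must be evenly spaced", call. = FALSE)
  }
  if (ncol(absorbance) != length(wavelengths)) {
    stop(sprintf(
      "absorbance has %d columns but there are %d wavelengths",
      ncol(absorbance), length(wavelengths)
    ), call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("scan_", seq_len(nrow(absorbance)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) == 1L && nrow(absorbance) > 1L) {
    sample_ids <- rep(sample_ids, nrow(absorbance))
  }
  if (length(sample_ids) != nrow(absorbance)) {
    stop("sample_ids length must match the number of scans", call. = FALSE)
  }
  colnames(absorbance) <- format(wavelengths, trim = TRUE)
  structure(
    list(
      wavelengths = wavelengths,
      absorbance = absorbance,
      sample_ids = sample_ids
    ),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf(
    "<spectra_set: %d scans x %d wavelengths (%.0f-%.0f nm, step %.3g nm)>\n",
    nrow(x$absorbance), length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths), mean(diff(x$wavelengths))
  ))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset the scans of a spectra set
#'
#' @param x A `spectra_set`.
#' @param i Row (scan) index.
#' @param ... Unused.
#' @return A `spectra_set` containing the selected scans.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$wavelengths, x$absorbance[i, , drop = FALSE], x$sample_ids[i])
}

#' Default near-infrared wavelength grid
#'
#' The instrument grid used throughout: 900 to 1700 nm at a 7 nm bandwidth,
#' giving 115 points (the last at 1698 nm).
#'
#' @param start,stop,step Grid parameters in nm.
#' @return Numeric vector of wavelengths.
#' @export
nir_grid <- function(start = 900, stop = 1700, step = 7) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  seq(start, stop, by = step)
}
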