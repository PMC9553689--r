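#' Standard normal variate (SNV) transformation
#'
#' Centers each scan to mean zero and scales it to unit standard deviation
#' (sample sd, denominator n-1). SNV removes per-scan additive baseline
#' offsets and multiplicative scatter: any transform `a * x + b` with
#' `a > 0` maps to the same output as `x`.
#'
#' @param spectra A [spectra_set()].
#' @return A `spectra_set` of the transformed scans.
#' @export
snv <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  A <- spectra$absorbance
  m <- rowMeans(A)
  s <- apply(A, 1L, stats::sd)
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad) > 0L) {
    stop(sprintf(
      "SNV undefined for constant scan(s): %s",
      paste(spectra$sample_ids[bad], collapse = ", ")
    ), call. = FALSE)
  }
  spectra_set(spectra$wavelengths, (A - m) / s, spectra$sample_ids)
}

# Savitzky-Golay weight row for one output position.
# idx: window column indices, centre: index (within idx) of the output point,
# x spacing taken as unit steps; derivative scaling applied by the caller.
sg_weights <- function(offsets, polyorder, deriv_order) {
  V <- outer(offsets, 0:polyorder, `^`)
  # row of (V'V)^{-1} V' picking the deriv_order-th polynomial coefficient,
  # times deriv_order! to turn the coefficient into a derivative value
  e <- numeric(polyorder + 1L)
  e[deriv_order + 1L] <- factorial(deriv_order)
  drop(e %*% solve(crossprod(V), t(V)))
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Local polynomial least-squares convolution applied scan by scan. With
#' `deriv_order = 0` the result is the smoothed spectrum; with
#' `deriv_order = 1` the first derivative with respect to wavelength
#' (divided by the grid step, so units are absorbance/nm). Points within
#' half a window of either end are handled by refitting the polynomial on
#' the truncated window rather than by padding, so no data are fabricated
#' at the spectrum ends.
#'
#' @param spectra A [spectra_set()].
#' @param window Odd window length in points.
#' @param polyorder Polynomial degree, `< window`.
#' @param deriv_order Derivative order, `0 <= deriv_order <= polyorder`.
#' @return A `spectra_set` of filtered scans.
#' @export
savitzky_golay <- function(spectra, window = 11L, polyorder = 2L,
                           deriv_order = 0L) {
  stopifnot(inherits(spectra, "spectra_set"))
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  deriv_order <- as.integer(deriv_order)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (window <= polyorder) stop("window must exceed polyorder", call. = FALSE)
  if (deriv_order < 0L || deriv_order > polyorder) {
    stop("need 0 <= deriv_order <= polyorder", call. = FALSE)
  }
  p <- length(spectra$wavelengths)
  if (window > p) stop("window exceeds the number of wavelengths", call. = FALSE)
  half <- (window - 1L) %/% 2L
  step <- mean(diff(spectra$wavelengths))

  # weight matrix W (p x p): out = scan %*% t(W); rows are per-position filters
  W <- matrix(0, p, p)
  central <- sg_weights(seq(-half, half), polyorder, deriv_order)
  for (j in seq_len(p)) {
    lo <- max(1L, j - half)
    hi <- min(p, j + half)
    if (lo == j - half && hi == j + half) {
      W[j, lo:hi] <- central
    } else {
      W[j, lo:hi] <- sg_weights(seq(lo, hi) - j, polyorder, deriv_order)
    }
  }
  out <- tcrossprod(spectra$absorbance, W) / step^deriv_order
  spectra_set(spectra$wavelengths, out, spectra$sample_ids)
}

#' Apply a named chain of pretreatments
#'
#' Convenience wrapper running pretreatment steps in order. Each element of
#' `chain` is either the string `"snv"` or `"sg"`, or a list
#' `list(op = "sg", window =, polyorder =, deriv_order =)`.
#'
#' @param spectra A [spectra_set()].
#' @param chain Character vector or list describing the steps, e.g.
#'   `c("sg", "snv")` (the default pipeline: smooth, then SNV).
#' @return The pretreated `spectra_set`.
#' @export
pretreat <- function(spectra, chain = c("sg", "snv")) {
  for (step in chain) {
    if (is.character(step)) step <- list(op = step)
    spectra <- switch(step$op,
      snv = snv(spectra),
      sg = savitzky_golay(
        spectra,
        window = step$window %||% 11L,
        polyorder = step$polyorder %||% 2L,
        deriv_order = step$deriv_order %||% 0L
      ),
      none = spectra,
      stop(sprintf("unknown pretreatment '%s'", step$op), call. = FALSE)
    )
  }
  spectra
}

`%||%` <- function(a, b) if (is.null(a)) b else a
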