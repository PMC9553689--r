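#' Fit a linear calibration curve to a standard series
#'
#' Ordinary (unweighted) least squares of detector response on
#' concentration: `response = slope * ppm + intercept`. With
#' `log_log = TRUE` the fit is instead `log(response) = b * log(ppm) + a`,
#' the power-law form sometimes used for evaporative light-scattering
#' detectors; the default stays linear, matching the usual reporting of a
#' single linear R-squared.
#'
#' @param series A `standard_series` (see [generate_standard_series()]) or
#'   any data.frame with `level_ppm` and `response` columns.
#' @param log_log Fit the power-law (log-log) form instead.
#' @return A `calibration_curve`: list with `slope`, `intercept`,
#'   `r_squared`, `analyte`, `range_ppm`, `log_log`.
#' @export
fit_calibration <- function(series, log_log = FALSE) {
  lev <- series$level_ppm
  resp <- series$response
  if (length(unique(lev)) < 2L) {
    stop("calibration needs at least two distinct levels", call. = FALSE)
  }
  if (log_log) {
    if (any(lev <= 0) || any(resp <= 0)) {
      stop("log-log calibration needs positive levels and responses",
        call. = FALSE
      )
    }
    fit <- stats::lm(log(resp) ~ log(lev))
  } else {
    fit <- stats::lm(resp ~ lev)
  }
  co <- stats::coef(fit)
  # suppressWarnings: summary.lm warns on numerically perfect fits
  r2 <- if (stats::var(resp) == 0) {
    1
  } else {
    suppressWarnings(summary(fit)$r.squared)
  }
  structure(
    list(
      slope = unname(co[2L]), intercept = unname(co[1L]),
      r_squared = r2,
      analyte = attr(series, "analyte") %||% "analyte",
      range_ppm = range(lev), log_log = log_log
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve %s: response = %.4g * ppm + %.4g, R2 = %.4f, range %g-%g ppm>\n",
    x$analyte, x$slope, x$intercept, x$r_squared,
    x$range_ppm[1L], x$range_ppm[2L]
  ))
  invisible(x)
}

#' Expected retention times of the standard analytes
#'
#' The eight-sugar HPLC-ELSD panel elutes in the order xylose, fructose,
#' sorbitol, galactose, glucose, sucrose, lactose, maltose (monosaccharides
#' and the sugar alcohol before the disaccharides); resveratrol is the
#' LC-MS/MS analyte (precursor 227 m/z, fragment ions 143 and 185 m/z,
#' carried as identity metadata only).
#'
#' @param method `"hplc_elsd"` (sugars), `"lcmsms"` (resveratrol) or
#'   `"all"`.
#' @return Named numeric vector of retention times in minutes.
#' @export
analyte_library <- function(method = c("hplc_elsd", "lcmsms", "all")) {
  method <- match.arg(method)
  sugars <- c(
    xylose = 9.34, fructose = 10.53, sorbitol = 11.84, galactose = 12.69,
    glucose = 13.45, sucrose = 19.08, lactose = 20.92, maltose = 21.65
  )
  resv <- c(resveratrol = 3.050)
  switch(method,
    hplc_elsd = sugars,
    lcmsms = resv,
    all = c(resv, sugars)
  )
}

#' Assign chromatogram peaks to analytes by retention time
#'
#' Each peak is matched to the nearest library analyte within `tolerance`
#' minutes. When several peaks fall inside one analyte's window, the
#' nearest wins and the others stay unassigned; an analyte is never
#' shared. A tolerance wide enough to make neighbouring library windows
#' overlap is rejected up front (it would make assignment ambiguous).
#'
#' @param peaks Data.frame with `retention_time` (min) and `area` columns.
#' @param library Named vector of expected retention times, e.g.
#'   [analyte_library()].
#' @param tolerance Match window half-width in minutes (default 0.15).
#' @return The peaks data.frame with an `analyte` column (`NA` where
#'   unassigned).
#' @export
assign_peaks <- function(peaks, library = analyte_library(), tolerance = 0.15) {
  if (tolerance <= 0) stop("tolerance must be positive", call. = FALSE)
  if (any(duplicated(names(library)))) {
    stop("library analyte names must be unique", call. = FALSE)
  }
  rt <- sort(unname(library))
  if (length(rt) > 1L && any(diff(rt) < 2 * tolerance)) {
    stop("tolerance makes library retention-time windows overlap; reduce it",
      call. = FALSE
    )
  }
  if (any(peaks$retention_time <= 0)) {
    stop("retention times must be positive", call. = FALSE)
  }
  peaks$analyte <- NA_character_
  for (an in names(library)) {
    d <- abs(peaks$retention_time - library[[an]])
    inside <- which(d <= tolerance & is.na(peaks$analyte))
    if (length(inside) > 0L) {
      peaks$analyte[inside[which.min(d[inside])]] <- an
    }
  }
  peaks
}

#' Quantify assigned peaks against their calibration curves
#'
#' Back-calculates the extract concentration
#' `ppm = (area - intercept) / slope` for every assigned peak, then
#' converts to an amount per 100 g of sample:
#' `ppm (mg/L) * extract_volume (L) * dilution / sample_mass (g) * 100`,
#' reported in mg/100 g for `basis = "flour"` or scaled to ug/100 g for
#' `basis = "oil"` (the resveratrol convention). Back-calculated
#' concentrations outside the curve's fitted range are flagged as
#' extrapolated; negative ones are reported as 0 with a warning.
#'
#' @param peaks Assigned peaks from [assign_peaks()].
#' @param curves Named list of `calibration_curve` objects, one per
#'   assigned analyte.
#' @param sample_mass_g Sample mass extracted, g.
#' @param extract_volume_ml Extraction volume, mL.
#' @param dilution Dilution factor applied before injection (default 1).
#' @param basis `"flour"` (sugars, mg/100 g) or `"oil"` (resveratrol,
#'   ug/100 g).
#' @return A `concentration_table` data.frame: `analyte`, `area`,
#'   `ppm_extract`, `amount_per_100g`, `unit`, `extrapolated`.
#' @export
quantify_sample <- function(peaks, curves, sample_mass_g, extract_volume_ml,
                            dilution = 1, basis = c("flour", "oil")) {
  basis <- match.arg(basis)
  if (sample_mass_g <= 0 || extract_volume_ml <= 0) {
    stop("sample mass and extract volume must be positive", call. = FALSE)
  }
  assigned <- peaks[!is.na(peaks$analyte), , drop = FALSE]
  missing_curves <- setdiff(assigned$analyte, names(curves))
  if (length(missing_curves) > 0L) {
    stop(sprintf(
      "no calibration curve for: %s",
      paste(missing_curves, collapse = ", ")
    ), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(assigned)), function(i) {
    an <- assigned$analyte[i]
    cv <- curves[[an]]
    if (isTRUE(cv$log_log)) {
      ppm <- exp((log(assigned$area[i]) - cv$intercept) / cv$slope)
    } else {
      if (cv$slope == 0) {
        stop(sprintf("zero calibration slope for %s", an), call. = FALSE)
      }
      ppm <- (assigned$area[i] - cv$intercept) / cv$slope
    }
    extrap <- ppm < cv$range_ppm[1L] || ppm > cv$range_ppm[2L]
    if (ppm < 0) {
      warning(sprintf(
        "%s: negative back-calculated concentration (%.4g ppm) reported as 0",
        an, ppm
      ), call. = FALSE)
      ppm <- 0
    }
    # ppm = mg/L in extract; amount in 100 g of sample
    mg_per_100g <- ppm * (extract_volume_ml / 1000) * dilution /
      sample_mass_g * 100
    amount <- if (basis == "oil") mg_per_100g * 1000 else mg_per_100g
    data.frame(
      analyte = an, area = assigned$area[i], ppm_extract = ppm,
      amount_per_100g = amount,
      unit = if (basis == "oil") "ug/100 g oil" else "mg/100 g flour",
      extrapolated = extrap
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(
      analyte = character(0), area = numeric(0), ppm_extract = numeric(0),
      amount_per_100g = numeric(0), unit = character(0),
      extrapolated = logical(0)
    )
  }
  class(out) <- c("concentration_table", "data.frame")
  out
}
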