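#' @name io
#' @title CSV interchange formats
#'
#' @description
#' Plain-CSV readers and writers for the pipeline's tables. All readers
#' validate headers and cell types and report malformed rows with their
#' position; write-then-read round-trips are stable to 12 significant
#' digits (values are written with full precision).
NULL

read_checked_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0L) {
    stop(sprintf("empty input file: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    stop(sprintf("no data rows in %s", path), call. = FALSE)
  }
  df
}

require_numeric <- function(df, cols, path) {
  for (cl in cols) {
    v <- df[[cl]]
    if (is.character(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(suppress) & !is.na(v) & v != "" &
        tolower(v) != "nd" & tolower(v) != "na")
      if (length(bad) > 0L) {
        stop(sprintf(
          "non-numeric value '%s' in column '%s', row %d of %s",
          v[bad[1L]], cl, bad[1L], path
        ), call. = FALSE)
      }
      df[[cl]] <- suppress
    }
  }
  df
}

no_duplicate_ids <- function(ids, path) {
  d <- ids[duplicated(ids)]
  if (length(d) > 0L) {
    stop(sprintf(
      "duplicate sample id(s) in %s: %s", path,
      paste(unique(d), collapse = ", ")
    ), call. = FALSE)
  }
}

#' Read and write spectra CSV
#'
#' Format: first column `sample_id`, remaining column headers are the
#' wavelengths in nm; one row per scan.
#'
#' @param path File path.
#' @return [spectra_set()] for the reader; the writer returns `path`
#'   invisibly.
#' @export
read_spectra_csv <- function(path) {
  df <- read_checked_csv(path)
  if (names(df)[1L] != "sample_id") {
    stop(sprintf("first column of %s must be 'sample_id'", path), call. = FALSE)
  }
  wl <- suppressWarnings(as.numeric(names(df)[-1L]))
  if (any(is.na(wl))) {
    stop(sprintf("non-numeric wavelength header in %s", path), call. = FALSE)
  }
  df <- require_numeric(df, names(df)[-1L], path)
  spectra_set(wl, as.matrix(df[, -1L, drop = FALSE]), df$sample_id)
}

#' @rdname read_spectra_csv
#' @param spectra A [spectra_set()].
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_set"))
  df <- data.frame(
    sample_id = spectra$sample_ids, spectra$absorbance,
    check.names = FALSE
  )
  names(df) <- c("sample_id", format(spectra$wavelengths, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write composition CSV
#'
#' Format: `sample_id, oil_pct, moisture_pct, ash_pct, protein_pct,
#' carbohydrate_pct`.
#'
#' @param path File path.
#' @return Data.frame for the reader; the writer returns `path` invisibly.
#' @export
read_composition_csv <- function(path) {
  df <- read_checked_csv(path)
  need <- c("sample_id", paste0(nutrient_names(), "_pct"))
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf(
      "%s is missing column(s): %s", path, paste(miss, collapse = ", ")
    ), call. = FALSE)
  }
  no_duplicate_ids(df$sample_id, path)
  require_numeric(df, setdiff(need, "sample_id"), path)[, need]
}

#' @rdname read_composition_csv
#' @param compositions Composition data.frame.
#' @export
write_composition_csv <- function(compositions, path) {
  utils::write.csv(compositions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an NMR peak-integral CSV
#'
#' Format: `sample_id, A, B, C, D, E`.
#'
#' @param path File path.
#' @return Data.frame with one [peak_integrals()]-compatible row per
#'   sample.
#' @export
read_integrals_csv <- function(path) {
  df <- read_checked_csv(path)
  need <- c("sample_id", "A", "B", "C", "D", "E")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf(
      "%s is missing column(s): %s", path, paste(miss, collapse = ", ")
    ), call. = FALSE)
  }
  no_duplicate_ids(df$sample_id, path)
  require_numeric(df, need[-1L], path)[, need]
}

#' Read a chromatogram peak-table CSV
#'
#' Format: `retention_time, area` (optionally `sample_id`).
#'
#' @param path File path.
#' @return Data.frame of peaks.
#' @export
read_peaks_csv <- function(path) {
  df <- read_checked_csv(path)
  miss <- setdiff(c("retention_time", "area"), names(df))
  if (length(miss) > 0L) {
    stop(sprintf(
      "%s is missing column(s): %s", path, paste(miss, collapse = ", ")
    ), call. = FALSE)
  }
  require_numeric(df, c("retention_time", "area"), path)
}

#' Read a standard-series CSV
#'
#' Format: `level_ppm, response` (optionally `analyte`).
#'
#' @param path File path.
#' @return A `standard_series` data.frame.
#' @export
read_standard_series_csv <- function(path) {
  df <- read_checked_csv(path)
  miss <- setdiff(c("level_ppm", "response"), names(df))
  if (length(miss) > 0L) {
    stop(sprintf(
      "%s is missing column(s): %s", path, paste(miss, collapse = ", ")
    ), call. = FALSE)
  }
  df <- require_numeric(df, c("level_ppm", "response"), path)
  structure(df,
    analyte = if ("analyte" %in% names(df)) df$analyte[1L] else "analyte",
    class = c("standard_series", "data.frame")
  )
}

#' Write a validation report as CSV
#'
#' One row per validated model with the ten error-suite columns
#' (`rmsec, sec, r2c, rmsecv, secv, r2cv, rmsep, sep, r2p, rpd`).
#'
#' @param report A `validation_report` (or several row-bound together).
#' @param path File path.
#' @export
write_validation_csv <- function(report, path) {
  df <- as.data.frame(report)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' The configuration names input paths, the pretreatment chain, the
#' model method and split (seed mandatory), the analyte library
#' tolerance and the significance level. Referenced files must exist.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in intersect(
    c("spectra_csv", "reference_csv", "integrals_csv", "peaks_csv"),
    names(cfg)
  )) {
    if (!file.exists(cfg[[key]])) {
      stop(sprintf("configured file does not exist: %s = %s", key, cfg[[key]]),
        call. = FALSE
      )
    }
  }
  stochastic <- !is.null(cfg$method) || !is.null(cfg$simulate)
  if (stochastic && is.null(cfg$seed)) {
    stop("config must set an explicit seed for stochastic steps", call. = FALSE)
  }
  cfg
}
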