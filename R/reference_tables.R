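#' @name reference_tables
#' @title Bundled reference dataset: six seed and nut samples
#'
#' @description
#' The package ships the published summary measurements for six seed and
#' nut samples — candlenut (`cnd`), peanut (`pnt`), sesame (`ssm`),
#' sunflower (`snf`), sacha inchi press residue (`inc`) and black bean
#' (`bkb`), plus red bean (`rdb`) in the proximate block — as plain-CSV
#' tables under `inst/extdata`. They serve as desk-scale inputs for the
#' fatty-acid, chromatographic and reporting stages, and as internal
#' consistency checks for the calibration error suite. `"nd"` cells (not
#' detected) are read as `NA`, never as zero.
#'
#' * `reference_nmr_profiles()` — fatty-acid class percentages
#'   (omega-3/6/9, SFA, PUFA) from 1H-NMR integral ratios.
#' * `reference_fame()` — FAME percentages by GC-FID, with the printed
#'   SFA/PUFA class totals in `sfa_pct`/`pufa_pct`.
#' * `reference_sugars()` — the eight-sugar panel, mg/100 g flour,
#'   mean and sd over replicates.
#' * `reference_resveratrol()` — resveratrol, ug/100 g oil.
#' * `reference_proximate()` — the five proximate nutrients, percent by
#'   mass, seven samples.
#' * `reference_nir_metrics()` — the NIR calibration error suite
#'   (RMSEC/SEC/R2C, RMSECV/SECV/R2CV, RMSEP/R2P/SEP, RPD) for PLS and
#'   PCR models of the five nutrients, n = 140 samples with a 20-sample
#'   random prediction set.
NULL

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "nutrispec")
  if (p == "") {
    # during development (package loaded via pkgload) fall back to source tree
    p <- file.path("inst", "extdata", file)
  }
  p
}

read_ref <- function(file) {
  df <- utils::read.csv(ref_path(file), stringsAsFactors = FALSE)
  for (cl in setdiff(names(df), c("sample_id", "nutrient", "analyte", "method"))) {
    if (is.character(df[[cl]])) {
      df[[cl]][tolower(df[[cl]]) == "nd"] <- NA
      df[[cl]] <- as.numeric(df[[cl]])
    }
  }
  df
}

#' @rdname reference_tables
#' @export
reference_nmr_profiles <- function() read_ref("seed_nut_nmr_profiles.csv")

#' @rdname reference_tables
#' @export
reference_fame <- function() read_ref("seed_nut_fame.csv")

#' @rdname reference_tables
#' @export
reference_sugars <- function() read_ref("seed_nut_sugars.csv")

#' @rdname reference_tables
#' @export
reference_resveratrol <- function() read_ref("seed_nut_resveratrol.csv")

#' @rdname reference_tables
#' @export
reference_proximate <- function() read_ref("seed_nut_proximate.csv")

#' @rdname reference_tables
#' @export
reference_nir_metrics <- function() read_ref("nir_model_metrics.csv")
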