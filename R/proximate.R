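#' Kjeldahl nitrogen percentage from a back-titration
#'
#' `(mL_sample - mL_blank) * normality * 14.007 * 100 / sample_mass_mg`:
#' the titrant equivalents difference times the atomic mass of nitrogen,
#' expressed as a mass percent of the sample. A sample titre below the
#' blank gives a negative value, which is returned with a quality warning
#' rather than clamped, so bad replicates remain visible downstream.
#'
#' @param ml_sample Titrant volume for the sample, mL.
#' @param ml_blank Titrant volume for the blank, mL.
#' @param normality Titrant normality, equivalents/L (typically 0.05 N).
#' @param sample_mass_mg Sample mass in mg.
#' @return Nitrogen, percent by mass.
#' @export
nitrogen_percent <- function(ml_sample, ml_blank, normality, sample_mass_mg) {
  if (any(sample_mass_mg <= 0)) stop("sample mass must be positive", call. = FALSE)
  if (any(normality <= 0)) stop("normality must be positive", call. = FALSE)
  if (any(ml_sample < 0) || any(ml_blank < 0)) {
    stop("titrant volumes must be >= 0", call. = FALSE)
  }
  out <- (ml_sample - ml_blank) * normality * 14.007 * 100 / sample_mass_mg
  if (any(out < 0)) {
    warning("sample titre below blank: negative nitrogen percent (check replicate)",
      call. = FALSE
    )
  }
  out
}

#' Protein from nitrogen
#'
#' Multiplies Kjeldahl nitrogen percent by a nitrogen-to-protein
#' conversion factor. The default factor of 1 reports the titration
#' output directly as protein, matching the workflow the bundled
#' reference tables were produced with; the conventional food factor 6.25
#' is available via the argument.
#'
#' @param nitrogen_pct Nitrogen, percent by mass.
#' @param conversion_factor Positive unitless factor (1 or 6.25 are the
#'   common choices).
#' @return Protein, percent by mass.
#' @export
protein_percent <- function(nitrogen_pct, conversion_factor = 1) {
  if (any(conversion_factor <= 0)) {
    stop("conversion factor must be positive", call. = FALSE)
  }
  nitrogen_pct * conversion_factor
}

#' Carbohydrate by difference
#'
#' `100 - (moisture + protein + oil + ash)`, the closure term of the
#' five-fraction proximate budget. A negative result (inputs summing past
#' 100) is returned with a warning flagging inconsistent inputs, so batch
#' processing survives bad replicates.
#'
#' @param moisture_pct,protein_pct,oil_pct,ash_pct Percent by mass, each
#'   in `[0, 100]`.
#' @return Carbohydrate, percent by mass.
#' @export
carbohydrate_by_difference <- function(moisture_pct, protein_pct, oil_pct,
                                       ash_pct) {
  inputs <- cbind(moisture_pct, protein_pct, oil_pct, ash_pct)
  if (any(inputs < 0 | inputs > 100)) {
    stop("proximate fractions must lie in [0, 100]", call. = FALSE)
  }
  out <- 100 - (moisture_pct + protein_pct + oil_pct + ash_pct)
  if (any(out < 0)) {
    warning("proximate fractions sum past 100: negative carbohydrate flagged",
      call. = FALSE
    )
  }
  out
}

#' Mass fraction from a gravimetric record
#'
#' For ash or extracted oil, the residue mass over the sample mass; in
#' `mode = "loss"` (moisture), the lost mass over the sample mass. All
#' three weighings must share units.
#'
#' @param container_mass Mass of the empty container.
#' @param container_plus_sample_mass Container plus fresh sample.
#' @param container_plus_residue_mass Container plus residue after
#'   treatment.
#' @param mode `"residue"` (ash, oil) or `"loss"` (moisture).
#' @return Percent by mass.
#' @export
mass_fraction_percent <- function(container_mass, container_plus_sample_mass,
                                  container_plus_residue_mass,
                                  mode = c("residue", "loss")) {
  mode <- match.arg(mode)
  sample_mass <- container_plus_sample_mass - container_mass
  residue_mass <- container_plus_residue_mass - container_mass
  if (any(sample_mass <= 0)) {
    stop("sample mass must be positive (container + sample must exceed container)",
      call. = FALSE
    )
  }
  if (any(residue_mass < 0) || any(residue_mass > sample_mass)) {
    stop("residue mass must lie between 0 and the sample mass", call. = FALSE)
  }
  frac <- if (mode == "residue") {
    residue_mass / sample_mass
  } else {
    (sample_mass - residue_mass) / sample_mass
  }
  100 * frac
}
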