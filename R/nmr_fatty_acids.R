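#' NMR peak integral set
#'
#' Holds the five 1H-NMR peak integrals used for fatty-acid class
#' quantification of an oil: A, terminal methyl protons of non-omega-3
#' acyl chains; B, omega-3 methyl protons; C, allylic protons; D,
#' alpha-carbonyl methylene protons; E, the polyunsaturation-diagnostic
#' proton region of unsaturated chains. Units are arbitrary but must be
#' consistent across the five peaks; every derived quantity is a ratio.
#'
#' @param A,B,C,D,E Non-negative integrals; `D > 0` and `A + B > 0`.
#' @return An object of class `peak_integrals`.
#' @export
peak_integrals <- function(A, B, C, D, E) {
  v <- c(A = A, B = B, C = C, D = D, E = E)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("integrals must be finite and >= 0", call. = FALSE)
  }
  if (D <= 0) stop("integral D must be positive", call. = FALSE)
  if (A + B <= 0) stop("A + B must be positive", call. = FALSE)
  structure(as.list(v), class = "peak_integrals")
}

# clamp small negative values (noise) to zero with a warning
clamp0 <- function(x, what) {
  if (x < 0) {
    warning(sprintf("%s computed as %.6g; clamped to 0", what, x),
      call. = FALSE
    )
    x <- 0
  }
  x
}

#' Omega-3 percentage from peak integrals
#'
#' `100 * B / (A + B)`: the omega-3 terminal methyl resonance is shifted
#' away from that of all other chains, so its share of the total methyl
#' integral is the molar share of omega-3 chains.
#'
#' @param p A [peak_integrals()].
#' @return Percent of total fatty acids.
#' @export
omega3_pct <- function(p) {
  stopifnot(inherits(p, "peak_integrals"))
  100 * p$B / (p$A + p$B)
}

#' Omega-6 percentage from peak integrals
#'
#' `100 * (E/D - 2B/(A+B))`: E/D counts double-bond-interrupting protons
#' per chain (two per omega-3 chain, one per omega-6), so subtracting
#' twice the omega-3 fraction leaves omega-6. Small negative values from
#' integration noise are clamped to 0 with a warning.
#'
#' @inheritParams omega3_pct
#' @return Percent of total fatty acids.
#' @export
omega6_pct <- function(p) {
  stopifnot(inherits(p, "peak_integrals"))
  clamp0(100 * (p$E / p$D - 2 * p$B / (p$A + p$B)), "omega-6 %")
}

#' Omega-9 percentage from peak integrals
#'
#' `100 * (C/(2D) - E/D + B/(A+B))`: allylic protons (four per
#' double-bond-bearing chain, hence C/(2D) = unsaturated fraction) minus
#' the polyunsaturated contribution leaves the monounsaturated (omega-9)
#' share. Clamped at 0 as in [omega6_pct()].
#'
#' @inheritParams omega3_pct
#' @return Percent of total fatty acids.
#' @export
omega9_pct <- function(p) {
  stopifnot(inherits(p, "peak_integrals"))
  clamp0(100 * (p$C / (2 * p$D) - p$E / p$D + p$B / (p$A + p$B)), "omega-9 %")
}

#' Saturated fatty-acid percentage from peak integrals
#'
#' `100 * (1 - C/(2D))`: chains with no allylic protons are saturated.
#'
#' @inheritParams omega3_pct
#' @return Percent of total fatty acids.
#' @export
sfa_pct <- function(p) {
  stopifnot(inherits(p, "peak_integrals"))
  clamp0(100 * (1 - p$C / (2 * p$D)), "SFA %")
}

#' Full fatty-acid profile from peak integrals
#'
#' Assembles the four class percentages, the PUFA total
#' (omega-3 + omega-6) and the omega-6:omega-3 ratio. The ratio is `NA`
#' (undefined) when omega-3 is zero or undetected, never infinite. The
#' four classes sum to 100 by algebraic construction.
#'
#' @inheritParams omega3_pct
#' @return A one-row data.frame with columns `omega3_pct`, `omega6_pct`,
#'   `omega9_pct`, `sfa_pct`, `pufa_pct`, `omega6_to_omega3`.
#' @export
profile_from_integrals <- function(p) {
  w3 <- omega3_pct(p)
  w6 <- omega6_pct(p)
  w9 <- omega9_pct(p)
  sf <- sfa_pct(p)
  data.frame(
    omega3_pct = w3, omega6_pct = w6, omega9_pct = w9, sfa_pct = sf,
    pufa_pct = w3 + w6,
    omega6_to_omega3 = if (w3 > 0) w6 / w3 else NA_real_
  )
}

#' Saturation class of the common fatty-acid methyl esters
#'
#' Maps FAME names to `"SFA"`, `"MUFA"` or `"PUFA"`.
#'
#' @return Named character vector.
#' @export
fame_classes <- function() {
  c(
    methyl_butyrate = "SFA", methyl_palmitate = "SFA",
    methyl_stearate = "SFA", methyl_arachidate = "SFA",
    methyl_behenate = "SFA",
    methyl_oleate = "MUFA",
    methyl_linoleate = "PUFA", methyl_gamma_linolenate = "PUFA"
  )
}

#' Aggregate a FAME composition table into SFA and PUFA totals
#'
#' SFA is the sum of the saturated esters (butyrate, palmitate, stearate,
#' arachidate, behenate); PUFA the sum of the polyunsaturated ones
#' (linoleate, gamma-linolenate). The monounsaturated oleate belongs to
#' neither total. `NA` entries (esters not detected) are dropped from the
#' sums, never imputed as zero.
#'
#' @param fame Data.frame with a `sample_id` column and one column per
#'   ester, named as in [fame_classes()]; percentages of total fatty
#'   acids.
#' @param classes Named class map, defaulting to [fame_classes()]; any
#'   ester column absent from the map is an error.
#' @return Data.frame with `sample_id`, `sfa_pct`, `pufa_pct`.
#' @export
aggregate_fame_classes <- function(fame, classes = fame_classes()) {
  esters <- setdiff(names(fame), "sample_id")
  if (length(esters) == 0L) {
    warning("empty FAME table: SFA and PUFA reported as 0", call. = FALSE)
    return(data.frame(
      sample_id = fame$sample_id %||% character(0),
      sfa_pct = numeric(0), pufa_pct = numeric(0)
    ))
  }
  unknown <- setdiff(esters, names(classes))
  if (length(unknown) > 0L) {
    stop(sprintf(
      "no saturation class for ester(s): %s",
      paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }
  sum_class <- function(row, cls) {
    cols <- esters[classes[esters] == cls]
    vals <- unlist(row[cols])
    if (all(is.na(vals))) 0 else sum(vals, na.rm = TRUE)
  }
  data.frame(
    sample_id = fame$sample_id,
    sfa_pct = vapply(seq_len(nrow(fame)), function(i) {
      sum_class(fame[i, ], "SFA")
    }, numeric(1L)),
    pufa_pct = vapply(seq_len(nrow(fame)), function(i) {
      sum_class(fame[i, ], "PUFA")
    }, numeric(1L))
  )
}
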