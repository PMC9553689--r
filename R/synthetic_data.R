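#' Pure-component band specification
#'
#' Describes one nutrient's pure-component near-infrared spectrum as a sum
#' of Gaussian absorption bands. The generator's spectra are linear
#' mixtures of these component spectra weighted by mass fraction, so
#' multivariate calibration has an exactly linear signal to recover.
#'
#' @param nutrient One of `"oil"`, `"moisture"`, `"ash"`, `"protein"`,
#'   `"carbohydrate"`.
#' @param band_centers Band centre wavelengths in nm, each within
#'   900-1700 nm.
#' @param band_widths Gaussian sigmas in nm, same length as centres.
#' @param band_amplitudes Positive unitless peak amplitudes, same length.
#' @return An object of class `component_band_spec`.
#' @export
component_band_spec <- function(nutrient, band_centers, band_widths,
                                band_amplitudes) {
  nutrient <- match.arg(nutrient, nutrient_names())
  n <- length(band_centers)
  if (length(band_widths) == 1L) band_widths <- rep(band_widths, n)
  if (length(band_amplitudes) == 1L) band_amplitudes <- rep(band_amplitudes, n)
  if (length(band_widths) != n || length(band_amplitudes) != n) {
    stop("band_centers, band_widths, band_amplitudes must have equal length",
      call. = FALSE
    )
  }
  if (any(band_centers < 900 | band_centers > 1700)) {
    stop("band centres must lie within 900-1700 nm", call. = FALSE)
  }
  if (any(band_widths <= 0) || any(band_amplitudes <= 0)) {
    stop("band widths and amplitudes must be positive", call. = FALSE)
  }
  structure(
    list(
      nutrient = nutrient, band_centers = as.numeric(band_centers),
      band_widths = as.numeric(band_widths),
      band_amplitudes = as.numeric(band_amplitudes)
    ),
    class = "component_band_spec"
  )
}

#' The five proximate nutrients, in canonical order
#' @return Character vector.
#' @export
nutrient_names <- function() {
  c("oil", "moisture", "ash", "protein", "carbohydrate")
}

#' Default component band specifications
#'
#' Band centres follow the wavelengths at which each nutrient's calibration
#' regression coefficients peak in this spectral region: oil 929, 1039,
#' 1208, 1386, 1700 nm; moisture 977, 1107, 1338, 1473 nm; ash 1149, 1305,
#' 1411, 1494 nm; protein 1153, 1308, 1411, 1494, 1673 nm; carbohydrate
#' 929, 1007, 1211, 1442, 1584, 1692 nm. Widths default to a 25 nm sigma
#' and amplitudes to 1, producing broad overlapping bands typical of NIR
#' overtone spectra. Note protein and ash bands nearly coincide, so the
#' synthetic problem reproduces the strong collinearity that makes
#' full-spectrum multivariate calibration necessary.
#'
#' @param width Common Gaussian sigma in nm.
#' @param amplitude Common peak amplitude.
#' @return Named list of [component_band_spec()] objects.
#' @export
default_band_specs <- function(width = 25, amplitude = 1) {
  centers <- list(
    oil = c(929, 1039, 1208, 1386, 1700),
    moisture = c(977, 1107, 1338, 1473),
    ash = c(1149, 1305, 1411, 1494),
    protein = c(1153, 1308, 1411, 1494, 1673),
    carbohydrate = c(929, 1007, 1211, 1442, 1584, 1692)
  )
  lapply(
    stats::setNames(nutrient_names(), nutrient_names()),
    function(nm) component_band_spec(nm, centers[[nm]], width, amplitude)
  )
}

#' Noise specification for the spectra generator
#'
#' Models the artefacts pretreatment is designed to remove: a per-scan
#' linear baseline (random slope and offset), a per-scan multiplicative
#' scatter factor, and white additive noise.
#'
#' @param baseline_slope_sd sd of the baseline slope, absorbance/nm.
#' @param baseline_offset_sd sd of the baseline offset, absorbance.
#' @param scatter_multiplier_sd sd of the multiplicative scatter term
#'   (scan is multiplied by `1 + scatter`).
#' @param additive_noise_sd sd of white noise, absorbance.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_slope_sd = 0, baseline_offset_sd = 0,
                       scatter_multiplier_sd = 0, additive_noise_sd = 0) {
  vals <- c(
    baseline_slope_sd, baseline_offset_sd,
    scatter_multiplier_sd, additive_noise_sd
  )
  if (any(vals < 0)) stop("noise sds must be >= 0", call. = FALSE)
  structure(
    list(
      baseline_slope_sd = baseline_slope_sd,
      baseline_offset_sd = baseline_offset_sd,
      scatter_multiplier_sd = scatter_multiplier_sd,
      additive_noise_sd = additive_noise_sd
    ),
    class = "noise_spec"
  )
}

#' Default composition sampling ranges
#'
#' Per-nutrient (min, max) mass-percent ranges spanning the observed
#' extremes across the seven seed/nut samples of the bundled reference
#' dataset (candlenut down to red bean).
#'
#' @return Named list of length-2 numeric vectors.
#' @export
default_composition_ranges <- function() {
  list(
    oil = c(0.2, 61), moisture = c(3, 14.5), ash = c(1.7, 5.2),
    protein = c(15.5, 48), carbohydrate = c(12.4, 63.7)
  )
}

#' Sample random proximate compositions that close to 100 percent
#'
#' Oil, moisture, ash and protein are drawn uniformly within their ranges;
#' carbohydrate closes the budget as `100 - sum(others)` (the
#' by-difference definition). Draws whose closure term falls outside the
#' carbohydrate range are rejected and redrawn.
#'
#' @param n_samples Number of compositions.
#' @param ranges Named list of (min, max) percent ranges for the five
#'   nutrients; see [default_composition_ranges()].
#' @param seed Integer seed; required for reproducibility.
#' @return A data.frame with `sample_id` and the five `<nutrient>_pct`
#'   columns; every row sums to exactly 100.
#' @export
generate_compositions <- function(n_samples,
                                  ranges = default_composition_ranges(),
                                  seed) {
  if (n_samples < 2L) stop("n_samples must be >= 2", call. = FALSE)
  nms <- nutrient_names()
  if (!all(nms %in% names(ranges))) {
    stop("ranges must name all five nutrients", call. = FALSE)
  }
  lo <- vapply(ranges[nms], `[`, numeric(1L), 1L)
  hi <- vapply(ranges[nms], `[`, numeric(1L), 2L)
  if (any(hi < lo)) stop("range max below min", call. = FALSE)
  if (sum(lo) > 100 || sum(hi) < 100) {
    stop("infeasible ranges: need sum(min) <= 100 <= sum(max)", call. = FALSE)
  }
  open <- nms[nms != "carbohydrate"]
  crange <- ranges$carbohydrate
  set.seed(as.integer(seed))
  out <- matrix(NA_real_, n_samples, 5L, dimnames = list(NULL, nms))
  filled <- 0L
  for (iter in seq_len(10000L)) {
    need <- n_samples - filled
    if (need == 0L) break
    draw <- vapply(
      open,
      function(nm) stats::runif(need, ranges[[nm]][1L], ranges[[nm]][2L]),
      numeric(need)
    )
    draw <- matrix(draw, nrow = need)
    carb <- 100 - rowSums(draw)
    ok <- carb >= crange[1L] & carb <= crange[2L]
    # degenerate carb range (min == max): accept within tolerance
    if (crange[1L] == crange[2L]) ok <- abs(carb - crange[1L]) < 1e-9
    k <- sum(ok)
    if (k > 0L) {
      out[filled + seq_len(k), open] <- draw[ok, , drop = FALSE]
      out[filled + seq_len(k), "carbohydrate"] <- carb[ok]
      filled <- filled + k
    }
  }
  if (filled < n_samples) {
    stop("rejection sampling failed: carbohydrate range too narrow for the other ranges",
      call. = FALSE
    )
  }
  df <- data.frame(sample_id = sprintf("s%03d", seq_len(n_samples)), out)
  names(df) <- c("sample_id", paste0(nms, "_pct"))
  df
}

# component spectra matrix: rows = nutrients (canonical order), cols = grid
component_spectra_matrix <- function(bands, grid) {
  nms <- nutrient_names()
  t(vapply(nms, function(nm) {
    b <- bands[[nm]]
    if (is.null(b)) stop(sprintf("missing band spec for '%s'", nm), call. = FALSE)
    rowSums(vapply(
      seq_along(b$band_centers),
      function(i) {
        b$band_amplitudes[i] *
          exp(-(grid - b$band_centers[i])^2 / (2 * b$band_widths[i]^2))
      },
      numeric(length(grid))
    ))
  }, numeric(length(grid))))
}

#' Generate synthetic NIR spectra from compositions
#'
#' Each scan is the Beer-Lambert-style linear mixture
#' `sum_nutrient (fraction/100) * pure component spectrum`, multiplied by a
#' per-scan scatter factor `1 + s`, plus a per-scan linear baseline and
#' additive white noise. With all noise sds zero the spectra are exactly
#' linear in composition.
#'
#' @param compositions Data.frame from [generate_compositions()] (columns
#'   `sample_id`, `<nutrient>_pct`).
#' @param bands Named list of [component_band_spec()], one per nutrient.
#' @param noise A [noise_spec()].
#' @param grid Wavelength grid in nm; default [nir_grid()].
#' @param replicates_per_sample Scans generated per composition row
#'   (default 18, the instrument's repetition count).
#' @param seed Integer seed.
#' @return A [spectra_set()] with `replicates_per_sample` scans per sample,
#'   labelled by `sample_id`.
#' @export
generate_nir_spectra <- function(compositions, bands = default_band_specs(),
                                 noise = noise_spec(), grid = nir_grid(),
                                 replicates_per_sample = 1L, seed) {
  comp_cols <- paste0(nutrient_names(), "_pct")
  if (!all(comp_cols %in% names(compositions))) {
    stop("compositions must have the five <nutrient>_pct columns", call. = FALSE)
  }
  K <- component_spectra_matrix(bands, grid) # 5 x p
  fr <- as.matrix(compositions[, comp_cols]) / 100 # n x 5
  clean <- fr %*% K # n x p
  n <- nrow(clean) * replicates_per_sample
  p <- length(grid)
  idx <- rep(seq_len(nrow(clean)), each = replicates_per_sample)
  set.seed(as.integer(seed))
  scatter <- stats::rnorm(n, 0, noise$scatter_multiplier_sd)
  slope <- stats::rnorm(n, 0, noise$baseline_slope_sd)
  offset <- stats::rnorm(n, 0, noise$baseline_offset_sd)
  eps <- matrix(stats::rnorm(n * p, 0, noise$additive_noise_sd), n, p)
  gshift <- grid - grid[1L]
  A <- clean[idx, , drop = FALSE] * (1 + scatter) +
    outer(slope, gshift) + offset + eps
  spectra_set(grid, A, compositions$sample_id[idx])
}

#' Invert a fatty-acid profile into consistent NMR peak integrals
#'
#' Constructs peak integrals A-E (terminal methyl of non-omega-3 chains,
#' omega-3 methyl, allylic, alpha-carbonyl methylene, polyunsaturation
#' diagnostic) that map forward to the given class percentages under the
#' integral-ratio equations, i.e. `B/(A+B) = omega3/100`,
#' `E/D = 2*omega3/100 + omega6/100`,
#' `C/(2D) = (omega3 + omega6 + omega9)/100`. `scale` fixes D (and A+B is
#' set equal to D), since the equations are invariant to overall scale.
#'
#' @param omega3_pct,omega6_pct,omega9_pct,sfa_pct Class percentages that
#'   must be non-negative and sum to 100 (within `1e-6`).
#' @param scale Positive value assigned to integral D.
#' @return A named list with integrals `A`, `B`, `C`, `D`, `E` (class
#'   `peak_integrals`).
#' @export
integrals_from_profile <- function(omega3_pct, omega6_pct, omega9_pct,
                                   sfa_pct, scale = 1) {
  p <- c(omega3_pct, omega6_pct, omega9_pct, sfa_pct)
  if (any(p < 0)) stop("profile percentages must be >= 0", call. = FALSE)
  if (abs(sum(p) - 100) > 1e-6) {
    stop("profile must sum to 100 (omega3 + omega6 + omega9 + SFA)", call. = FALSE)
  }
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  D <- scale
  B <- scale * omega3_pct / 100
  A <- scale - B
  E <- D * (2 * omega3_pct + omega6_pct) / 100
  C <- 2 * D * (omega3_pct + omega6_pct + omega9_pct) / 100
  peak_integrals(A = A, B = B, C = C, D = D, E = E)
}

#' Generate a noisy chromatographic standard series
#'
#' Linear detector model: `response = slope * level + intercept + noise`.
#'
#' @param true_slope Response per ppm.
#' @param true_intercept Response at zero concentration.
#' @param levels Standard concentrations in ppm (mg/L); at least two
#'   distinct, all positive.
#' @param noise_sd sd of additive response noise.
#' @param seed Integer seed.
#' @param analyte Analyte name carried in the output.
#' @return A `standard_series`: data.frame with columns `level_ppm`,
#'   `response` and attribute `analyte`.
#' @export
generate_standard_series <- function(true_slope, true_intercept,
                                     levels = seq(100, 1200, by = 100),
                                     noise_sd = 0, seed, analyte = "analyte") {
  levels <- as.numeric(levels)
  if (any(levels <= 0)) stop("standard levels must be positive", call. = FALSE)
  if (length(unique(levels)) < 2L) {
    stop("need at least two distinct standard levels", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  resp <- true_slope * levels + true_intercept +
    stats::rnorm(length(levels), 0, noise_sd)
  structure(
    data.frame(level_ppm = levels, response = resp),
    analyte = analyte, class = c("standard_series", "data.frame")
  )
}
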