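#!/usr/bin/env Rscript
# Stage 1 — simulate the study's NIR dataset.
#
# Generates 140 proximate compositions spanning the observed extremes of
# the reference samples (oil 0.2-61 %, etc., carbohydrate closing each row
# to 100 %), then renders one mean spectrum per sample on the 900-1700 nm
# / 7 nm grid as a linear Beer-Lambert mixture of the five pure-component
# band spectra, with baseline drift, multiplicative scatter and additive
# noise at the documented study-condition levels. Writes both CSVs under
# results/.

suppressPackageStartupMessages(library(nutrispec))

seed <- 20260919L
dir.create("results", showWarnings = FALSE)

comp <- generate_compositions(140, seed = seed)
noise <- noise_spec(
  baseline_slope_sd = 1e-5, baseline_offset_sd = 0.02,
  scatter_multiplier_sd = 0.05, additive_noise_sd = 0.002
)
spectra <- generate_nir_spectra(comp, noise = noise, seed = seed + 1L)

write_composition_csv(comp, "results/synthetic_reference.csv")
write_spectra_csv(spectra, "results/synthetic_spectra.csv")

cat(sprintf(
  "simulated %d samples x %d wavelengths (%.0f-%.0f nm)\n",
  nrow(spectra$absorbance), length(spectra$wavelengths),
  min(spectra$wavelengths), max(spectra$wavelengths)
))
cat("composition ranges realized:\n")
for (nut in nutrient_names()) {
  v <- comp[[paste0(nut, "_pct")]]
  cat(sprintf("  %-12s %6.2f - %6.2f %%\n", nut, min(v), max(v)))
}
stopifnot(all(abs(rowSums(comp[, -1]) - 100) < 1e-9))
cat("every composition closes to 100 % (carbohydrate by difference)\n")
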