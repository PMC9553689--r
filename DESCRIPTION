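Package: nutrispec
Title: Seed and Nut Nutritional Quantification by NIR Chemometrics, NMR and
    Chromatographic Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantifying the nutritional composition of
    seeds and nuts from instrument summaries. Covers near-infrared (NIR)
    multivariate calibration of the five proximate nutrients (oil, moisture,
    ash, protein, carbohydrate) with Savitzky-Golay and standard normal
    variate pretreatment, NIPALS partial least squares and principal
    component regression, and the full calibration / cross-validation /
    prediction error suite with RPD model assessment; fatty-acid class
    percentages (omega-3, omega-6, omega-9, saturated) from 1H-NMR peak
    integral ratios with FAME class aggregation; Kjeldahl nitrogen,
    gravimetric mass-fraction and carbohydrate-by-difference proximate
    formulas; linear calibration-curve quantification of an eight-sugar
    HPLC-ELSD panel and of resveratrol with retention-time peak assignment;
    replicate aggregation with one-way ANOVA and pairwise significance; and
    a synthetic-data generator producing linear-mixture spectra, integral
    tables and detector responses with the statistical structure the
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr,
    jsonlite
Config/testthat/edition: 3
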