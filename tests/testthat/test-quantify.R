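test_that("two-point calibration is the exact interpolating line", {
  s <- structure(
    data.frame(level_ppm = c(100, 500), response = c(30, 110)),
    class = c("standard_series", "data.frame"), analyte = "xylose"
  )
  cv <- fit_calibration(s)
  expect_equal(cv$slope, 0.2)
  expect_equal(cv$intercept, 10)
  expect_equal(cv$r_squared, 1)
  expect_equal(cv$analyte, "xylose")
  expect_equal(cv$range_ppm, c(100, 500))
  expect_error(
    fit_calibration(data.frame(level_ppm = c(5, 5), response = c(1, 2))),
    "distinct"
  )
})

test_that("a realistic 12-level series fits with high R-squared in most seeds", {
  hits <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    s <- generate_standard_series(2, 5,
      levels = seq(100, 1200, 100),
      noise_sd = 40, seed = 1000 + i
    )
    if (fit_calibration(s)$r_squared >= 0.99) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("log-log option recovers a power-law detector response", {
  lev <- seq(100, 1200, 100)
  s <- structure(
    data.frame(level_ppm = lev, response = 3 * lev^1.4),
    class = c("standard_series", "data.frame"), analyte = "sugar"
  )
  cv <- fit_calibration(s, log_log = TRUE)
  expect_equal(cv$slope, 1.4, tolerance = 1e-9)
  expect_equal(cv$intercept, log(3), tolerance = 1e-9)
})

test_that("peaks are assigned to the nearest analyte within tolerance", {
  peaks <- data.frame(
    retention_time = c(19.10, 15.0, 9.30),
    area = c(100, 50, 80)
  )
  out <- assign_peaks(peaks, tolerance = 0.2)
  expect_equal(out$analyte, c("sucrose", NA, "xylose"))
  # exact library times: all assigned, elution order preserved
  lib <- analyte_library()
  exact <- data.frame(retention_time = unname(lib), area = 1)
  got <- assign_peaks(exact)$analyte
  expect_equal(got, names(lib))
  mono <- c("xylose", "fructose", "sorbitol", "galactose", "glucose")
  di <- c("sucrose", "lactose", "maltose")
  expect_true(max(match(mono, got)) < min(match(di, got)))
})

test_that("one analyte is never shared; nearest peak wins", {
  peaks <- data.frame(retention_time = c(19.02, 19.10), area = c(1, 2))
  out <- assign_peaks(peaks, tolerance = 0.15)
  expect_equal(out$analyte, c(NA, "sucrose"))
})

test_that("overlapping windows are rejected at configuration time", {
  expect_error(assign_peaks(
    data.frame(retention_time = 10, area = 1),
    tolerance = 0.5
  ), "overlap")
  expect_error(assign_peaks(
    data.frame(retention_time = 10, area = 1),
    tolerance = -1
  ), "positive")
})

test_that("quantification inverts the generator and converts units", {
  # a 500 ppm extract measured with its own curve: 1 g in 10 mL
  cv <- fit_calibration(generate_standard_series(2, 5,
    levels = seq(100, 1200, 100), seed = 3, analyte = "sucrose"
  ))
  area <- 2 * 500 + 5
  peaks <- assign_peaks(
    data.frame(retention_time = 19.08, area = area),
    tolerance = 0.15
  )
  tab <- quantify_sample(peaks, list(sucrose = cv),
    sample_mass_g = 1, extract_volume_ml = 10
  )
  expect_equal(tab$ppm_extract, 500, tolerance = 1e-9)
  expect_equal(tab$amount_per_100g, 500, tolerance = 1e-9) # mg/100 g flour
  expect_equal(tab$unit, "mg/100 g flour")
  expect_false(tab$extrapolated)
  # doubling the extract volume doubles the reported amount
  tab2 <- quantify_sample(peaks, list(sucrose = cv),
    sample_mass_g = 1, extract_volume_ml = 20
  )
  expect_equal(tab2$amount_per_100g, 2 * tab$amount_per_100g)
  # oil basis reports in ug/100 g
  tab3 <- quantify_sample(peaks, list(sucrose = cv),
    sample_mass_g = 1, extract_volume_ml = 10, basis = "oil"
  )
  expect_equal(tab3$amount_per_100g, 500 * 1000)
  expect_equal(tab3$unit, "ug/100 g oil")
})

test_that("blank areas, extrapolation and negative concentrations are flagged", {
  cv <- fit_calibration(generate_standard_series(2, 5,
    levels = seq(100, 1200, 100), seed = 4, analyte = "glucose"
  ))
  blank <- assign_peaks(
    data.frame(retention_time = 13.45, area = cv$intercept),
    tolerance = 0.15
  )
  tab <- quantify_sample(blank, list(glucose = cv), 1, 10)
  expect_equal(tab$ppm_extract, 0)
  expect_true(tab$extrapolated) # 0 ppm is below the 100 ppm curve floor
  neg <- assign_peaks(
    data.frame(retention_time = 13.45, area = cv$intercept - 10),
    tolerance = 0.15
  )
  expect_warning(tabn <- quantify_sample(neg, list(glucose = cv), 1, 10), "negative")
  expect_equal(tabn$amount_per_100g, 0)
  expect_error(
    quantify_sample(blank, list(), 1, 10),
    "no calibration curve"
  )
  expect_error(quantify_sample(blank, list(glucose = cv), 0, 10), "positive")
})

test_that("noiseless responses back-calculate to the true concentration", {
  cv <- fit_calibration(generate_standard_series(3.7, -12,
    levels = seq(100, 1200, 100), seed = 5, analyte = "fructose"
  ))
  truth <- c(150, 700, 1100)
  peaks <- data.frame(retention_time = rep(10.53, 3), area = 3.7 * truth - 12)
  peaks$analyte <- "fructose"
  tab <- quantify_sample(peaks, list(fructose = cv), 1, 10)
  expect_equal(tab$ppm_extract, truth, tolerance = 1e-9)
})
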