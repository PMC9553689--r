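test_that("generated compositions close to 100, respect ranges, and are seed-stable", {
  comp <- generate_compositions(140, seed = 11)
  expect_equal(nrow(comp), 140L)
  sums <- rowSums(comp[, paste0(nutrient_names(), "_pct")])
  expect_equal(sums, rep(100, 140))
  rg <- default_composition_ranges()
  for (nm in nutrient_names()) {
    v <- comp[[paste0(nm, "_pct")]]
    expect_true(all(v >= rg[[nm]][1] - 1e-12 & v <= rg[[nm]][2] + 1e-12))
  }
  expect_identical(comp, generate_compositions(140, seed = 11))
})

test_that("degenerate ranges force a single exact composition", {
  rg <- list(
    oil = c(40, 40), moisture = c(10, 10), ash = c(5, 5),
    protein = c(20, 20), carbohydrate = c(25, 25)
  )
  comp <- generate_compositions(5, ranges = rg, seed = 2)
  for (nm in nutrient_names()) {
    expect_equal(comp[[paste0(nm, "_pct")]], rep(rg[[nm]][1], 5))
  }
})

test_that("infeasible composition ranges are rejected", {
  rg <- default_composition_ranges()
  rg$oil <- c(90, 95)
  rg$protein <- c(90, 95) # sum of minima > 100
  expect_error(generate_compositions(10, ranges = rg, seed = 1), "nfeasible")
  expect_error(generate_compositions(1, seed = 1), ">= 2")
})

test_that("noise-free spectra are exactly linear in composition", {
  bands <- default_band_specs()
  grid <- nir_grid()
  pure <- function(nutrient) {
    comp <- data.frame(sample_id = "x", t(setNames(
      as.numeric(nutrient_names() == nutrient) * 100,
      paste0(nutrient_names(), "_pct")
    )))
    generate_nir_spectra(comp, bands, grid = grid, seed = 1)$absorbance[1, ]
  }
  oil <- pure("oil")
  b <- bands$oil
  expected <- rowSums(sapply(seq_along(b$band_centers), function(i) {
    b$band_amplitudes[i] * exp(-(grid - b$band_centers[i])^2 /
      (2 * b$band_widths[i]^2))
  }))
  expect_equal(oil, expected, tolerance = 1e-12, ignore_attr = TRUE)

  # 50/50 mix equals the mean of the pure spectra
  moisture <- pure("moisture")
  comp_mix <- data.frame(
    sample_id = "m", oil_pct = 50, moisture_pct = 50, ash_pct = 0,
    protein_pct = 0, carbohydrate_pct = 0
  )
  mix <- generate_nir_spectra(comp_mix, bands, grid = grid, seed = 1)
  expect_equal(mix$absorbance[1, ], (oil + moisture) / 2,
    tolerance = 1e-12, ignore_attr = TRUE
  )
})

test_that("spectra generation replicates samples, is seed-stable, and checks bands", {
  comp <- generate_compositions(5, seed = 3)
  sp <- generate_nir_spectra(comp,
    noise = study_noise(),
    replicates_per_sample = 18L, seed = 4
  )
  expect_equal(nrow(sp$absorbance), 5L * 18L)
  expect_equal(sp$sample_ids, rep(comp$sample_id, each = 18L))
  sp2 <- generate_nir_spectra(comp,
    noise = study_noise(),
    replicates_per_sample = 18L, seed = 4
  )
  expect_identical(sp$absorbance, sp2$absorbance)
  bands <- default_band_specs()
  bands$protein <- NULL
  expect_error(
    generate_nir_spectra(comp, bands, seed = 1),
    "missing band spec for 'protein'"
  )
})

test_that("component band spec validates its invariants", {
  expect_error(component_band_spec("oil", c(800), 25, 1), "900-1700")
  expect_error(component_band_spec("oil", c(1000, 1100), c(25), c(1, 1, 1)), "equal length")
  expect_error(component_band_spec("oil", 1000, -5, 1), "positive")
  ok <- component_band_spec("oil", c(929, 1039), 25, 1)
  expect_length(ok$band_widths, 2L)
})

test_that("profile inversion produces integrals satisfying the defining ratios", {
  p <- integrals_from_profile(23.310, 42.046, 22.480, 12.164, scale = 7)
  expect_equal(p$D, 7)
  expect_equal(p$B / (p$A + p$B), 0.23310, tolerance = 1e-12)
  expect_equal(p$E / p$D, 2 * 0.23310 + 0.42046, tolerance = 1e-12)
  expect_equal(p$C / (2 * p$D), (23.310 + 42.046 + 22.480) / 100,
    tolerance = 1e-12
  )
  # fully saturated: no omega-3/allylic/polyunsaturation signal
  sat <- integrals_from_profile(0, 0, 0, 100)
  expect_equal(c(sat$B, sat$C, sat$E), c(0, 0, 0))
  expect_error(integrals_from_profile(50, 30, 10, 5), "sum to 100")
  expect_error(integrals_from_profile(-1, 61, 20, 20), ">= 0")
})

test_that("forward mapping inverts integrals_from_profile over random profiles", {
  profs <- random_profiles(1000L, seed = 77)
  for (i in seq_len(nrow(profs))) {
    p <- integrals_from_profile(
      profs[i, 1], profs[i, 2], profs[i, 3], profs[i, 4]
    )
    got <- profile_from_integrals(p)
    expect_equal(
      c(got$omega3_pct, got$omega6_pct, got$omega9_pct, got$sfa_pct),
      unname(profs[i, ]),
      tolerance = 1e-12
    )
  }
})

test_that("standard series generator is linear, seed-stable, and validated", {
  s <- generate_standard_series(2, 5, levels = c(100, 400, 800), seed = 6)
  expect_equal(s$response, 2 * c(100, 400, 800) + 5)
  cv <- fit_calibration(s)
  expect_equal(cv$slope, 2, tolerance = 1e-12)
  expect_equal(cv$intercept, 5, tolerance = 1e-12)
  s2 <- generate_standard_series(2, 5,
    levels = seq(100, 1200, 100),
    noise_sd = 40, seed = 8
  )
  expect_identical(
    s2,
    generate_standard_series(2, 5,
      levels = seq(100, 1200, 100),
      noise_sd = 40, seed = 8
    )
  )
  expect_error(generate_standard_series(2, 5, levels = c(500, 500), seed = 1),
    regexp = "distinct"
  )
  expect_error(generate_standard_series(2, 5, levels = c(-5, 100), seed = 1),
    regexp = "positive"
  )
})
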