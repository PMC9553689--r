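test_that("full-rank PLS and PCR coefficients equal the least-squares oracle", {
  set.seed(31)
  n <- 25L
  p <- 6L
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  b_ols <- unname(coef(lm(y ~ X))[-1L])
  for (fit in list(fit_pls, fit_pcr)) {
    m <- fit(X, y, p)
    expect_equal(m$coefficients, b_ols, tolerance = 1e-8)
    expect_equal(predict(m, X), unname(fitted(lm(y ~ X))), tolerance = 1e-8)
  }
})

test_that("PLS coefficient path reproduces the score/loading prediction", {
  set.seed(32)
  X <- matrix(rnorm(40 * 12), 40, 12)
  y <- rnorm(40)
  m <- fit_pls(X, y, 4)
  via_scores <- drop(m$scores %*% m$q) + m$y_mean
  expect_equal(predict(m, X), via_scores, tolerance = 1e-10)
})

test_that("PLS deflation leaves residual X orthogonal to extracted weights", {
  set.seed(33)
  X <- matrix(rnorm(30 * 20), 30, 20)
  y <- rnorm(30)
  m <- fit_pls(X, y, 6)
  expect_lt(max(abs(m$x_residual %*% m$W)), 1e-10)
  # scores are mutually orthogonal too
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("PCR with one dominant direction aligns with it; signs deterministic", {
  set.seed(34)
  v <- c(3, 1, -2, 0.5)
  v <- v / sqrt(sum(v^2))
  scores <- rnorm(50, sd = 10)
  X <- outer(scores, v) + matrix(rnorm(200, sd = 1e-3), 50, 4)
  y <- scores + rnorm(50, sd = 1e-3)
  m <- fit_pcr(X, y, 1)
  cosang <- sum(m$coefficients * v) /
    sqrt(sum(m$coefficients^2) * sum(v^2))
  expect_gt(abs(cosang), 1 - 1e-4)
  m2 <- fit_pcr(X[sample(50), ], y, 1) # refit: same sign convention
  expect_gt(m$V[which.max(abs(m$V[, 1])), 1], 0)
  expect_gt(m2$V[which.max(abs(m2$V[, 1])), 1], 0)
})

test_that("noise-free linear mixtures are recovered exactly by both models", {
  comp <- generate_compositions(60, seed = 41)
  sp <- generate_nir_spectra(comp, seed = 42)
  split <- split_spec(n_holdout = 10, seed = 43)
  for (method in c("pls", "pcr")) {
    for (nut in c("oil", "protein")) {
      r <- validate(sp, comp[[paste0(nut, "_pct")]], method, k = 4, split = split)
      expect_lt(r$rmsep, 1e-6)
      expect_lt(r$rmsec, 1e-6)
      expect_gt(r$r2p, 1 - 1e-9)
    }
  }
})

test_that("PLS and PCR agree on the noise-free problem", {
  comp <- generate_compositions(40, seed = 44)
  sp <- generate_nir_spectra(comp, seed = 45)
  y <- comp$oil_pct
  p1 <- predict(fit_pls(sp, y, 4), sp)
  p2 <- predict(fit_pcr(sp, y, 4), sp)
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("rank and alignment violations error", {
  comp <- generate_compositions(20, seed = 46)
  sp <- generate_nir_spectra(comp, seed = 47)
  # closure makes centered rank 4: a 5th component must fail
  expect_error(fit_pls(sp, comp$oil_pct, 5), "reduce k")
  expect_error(fit_pcr(sp, comp$oil_pct, 5), "rank")
  expect_error(fit_pls(sp, comp$oil_pct[-1], 2), "row-aligned")
  expect_error(fit_pls(sp, comp$oil_pct, 0), ">= 1")
  expect_error(fit_pls(sp, comp$oil_pct, 50), "exceeds")
})

test_that("predicting at the training mean returns the training mean response", {
  set.seed(48)
  X <- matrix(rnorm(60), 15, 4)
  y <- rnorm(15)
  m <- fit_pls(X, y, 2)
  at_mean <- matrix(m$x_mean, nrow = 3, ncol = 4, byrow = TRUE)
  expect_equal(predict(m, at_mean), rep(m$y_mean, 3), tolerance = 1e-12)
})

test_that("predict enforces the wavelength grid", {
  comp <- generate_compositions(15, seed = 49)
  sp <- generate_nir_spectra(comp, seed = 50)
  m <- fit_pls(sp, comp$oil_pct, 3)
  other <- spectra_set(sp$wavelengths + 1, sp$absorbance)
  expect_error(predict(m, other), "grid")
  expect_error(predict(m, matrix(0, 2, 10)), "wrong number of wavelengths")
})

test_that("validation report carries the RPD identity and sane metrics", {
  comp <- generate_compositions(80, seed = 51)
  sp <- generate_nir_spectra(comp, noise = study_noise(), seed = 52)
  sp <- pretreat(sp)
  split <- split_spec(20, seed = 53)
  r <- validate(sp, comp$oil_pct, "pls", k = 4, split = split)
  hold <- attr(r, "holdout")
  expect_equal(r$rpd, sd(comp$oil_pct[hold]) / r$sep, tolerance = 1e-9)
  expect_true(all(c(r$rmsec, r$sec, r$rmsecv, r$secv, r$rmsep, r$sep) >= 0))
  expect_true(all(c(r$r2c, r$r2cv, r$r2p) >= 0 & c(r$r2c, r$r2cv, r$r2p) <= 1))
  expect_equal(r$n_cal + r$n_val, 80L)
  expect_error(
    validate(sp, comp$oil_pct, "pls",
      k = 4,
      split = split_spec(1, seed = 1)
    ),
    ">= 2"
  )
})

test_that("shuffled labels destroy cross-validated skill (permutation null)", {
  comp <- generate_compositions(60, seed = 54)
  sp <- generate_nir_spectra(comp, noise = study_noise(), seed = 55)
  set.seed(56)
  y_perm <- sample(comp$oil_pct)
  r <- validate(sp, y_perm, "pls", k = 3, split = split_spec(15, seed = 57))
  expect_lt(r$r2cv, 0.2)
  expect_lt(r$rpd, 1.6)
})

test_that("component selection finds the exact-recovery k on noise-free data", {
  comp <- generate_compositions(50, seed = 58)
  sp <- generate_nir_spectra(comp, seed = 59)
  sel <- select_components(sp, comp$oil_pct, "pls",
    split = split_spec(10, seed = 60), k_max = 8
  )
  expect_lte(sel$k, 4L)
  expect_lt(min(sel$rmsecv, na.rm = TRUE), 1e-6)
})

test_that("calibration RMSEC is non-increasing in the number of components", {
  set.seed(61)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- rnorm(40)
  rmsec <- sapply(1:8, function(k) {
    m <- fit_pls(X, y, k)
    sqrt(mean((y - predict(m, X))^2))
  })
  expect_true(all(diff(rmsec) <= 1e-10))
})

test_that("pure-noise response selects a small model with RMSECV near sd(y)", {
  comp <- generate_compositions(60, seed = 62)
  sp <- generate_nir_spectra(comp, seed = 63)
  set.seed(64)
  y_noise <- rnorm(60)
  sel <- select_components(sp, y_noise, "pls",
    split = split_spec(10, seed = 65), k_max = 6
  )
  expect_lt(abs(sel$rmsecv[sel$k] - sd(y_noise)), 0.5 * sd(y_noise))
})

test_that("prediction error scales linearly with additive noise level", {
  comp <- generate_compositions(80, seed = 66)
  sds <- c(0.002, 0.004, 0.008, 0.016)
  rmsep <- sapply(seq_along(sds), function(i) {
    sp <- generate_nir_spectra(comp,
      noise = noise_spec(additive_noise_sd = sds[i]), seed = 70 + i
    )
    validate(sp, comp$oil_pct, "pls",
      k = 4,
      split = split_spec(20, seed = 80)
    )$rmsep
  })
  fit <- lm(rmsep ~ sds)
  expect_gt(summary(fit)$r.squared, 0.95)
  expect_lt(abs(coef(fit)[1]), 0.5 * max(rmsep)) # near-zero intercept
})

test_that("RPD bands classify published and boundary values correctly", {
  expect_equal(classify_rpd(13.208), "excellent")
  expect_equal(classify_rpd(2.886), "very reliable")
  expect_equal(classify_rpd(1.0), "unreliable")
  expect_equal(
    classify_rpd(c(0, 1.5, 2, 3, 100)),
    c("unreliable", "limited", "very reliable", "excellent", "excellent")
  )
  expect_error(classify_rpd(-0.1), "negative")
  expect_error(classify_rpd(2, thresholds = c(3, 2, 1)), "increasing")
})

test_that("split_spec demands a seed and validates holdout size", {
  expect_error(split_spec(20), "seed")
  expect_error(split_spec(0, seed = 1), ">= 1")
})
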