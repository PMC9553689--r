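# Shared fixture builders. Everything is generated in code at test time.

# a small spectra_set with reproducible random scans
make_random_spectra <- function(n_scans = 3L, n_wl = 40L, seed = 99L) {
  set.seed(seed)
  wl <- seq(900, by = 7, length.out = n_wl)
  spectra_set(wl, matrix(rnorm(n_scans * n_wl), n_scans, n_wl))
}

# random valid fatty-acid profiles (four classes summing to 100)
random_profiles <- function(n, seed = 123L) {
  set.seed(seed)
  x <- matrix(rexp(4L * n), n, 4L)
  x <- 100 * x / rowSums(x)
  colnames(x) <- c("omega3", "omega6", "omega9", "sfa")
  x
}

# brute-force Savitzky-Golay: per-point local polynomial regression
sg_bruteforce <- function(x, y, window, polyorder, deriv_order = 0L) {
  half <- (window - 1L) %/% 2L
  n <- length(y)
  out <- numeric(n)
  for (j in seq_len(n)) {
    lo <- max(1L, j - half)
    hi <- min(n, j + half)
    fit <- lm(y[lo:hi] ~ poly(x[lo:hi] - x[j], degree = polyorder, raw = TRUE))
    out[j] <- coef(fit)[deriv_order + 1L] * factorial(deriv_order)
  }
  out
}

# the small default noisy study conditions used for end-to-end checks
study_noise <- function() {
  noise_spec(
    baseline_slope_sd = 1e-5, baseline_offset_sd = 0.02,
    scatter_multiplier_sd = 0.05, additive_noise_sd = 0.002
  )
}
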