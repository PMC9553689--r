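#' @name chemometrics
#' @title Multivariate calibration of nutrient content against NIR spectra
#'
#' @description
#' Full-spectrum calibration relates a nutrient's reference values `y`
#' (percent by mass) to absorbance spectra `X` through a linear model
#' `y = (X - x_mean) b + y_mean` whose coefficient vector `b` is estimated
#' either by partial least squares (PLS, sequential NIPALS latent
#' variables maximizing covariance with `y`) or by principal component
#' regression (PCR, least squares on the leading principal-component
#' scores). Only centering is applied: SNV pretreatment already normalizes
#' the scans, and `y` is centered but not scaled.
NULL

# coerce a spectra_set or bare matrix to the predictor matrix
x_matrix <- function(X) {
  if (inherits(X, "spectra_set")) X$absorbance else as.matrix(X)
}

x_wavelengths <- function(X) {
  if (inherits(X, "spectra_set")) X$wavelengths else NULL
}

new_calibration_model <- function(method, k, x_mean, y_mean, coefficients,
                                  wavelengths, extra = list()) {
  structure(
    c(
      list(
        method = method, n_components = k, x_mean = x_mean, y_mean = y_mean,
        coefficients = as.numeric(coefficients), wavelengths = wavelengths
      ),
      extra
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model: %s, %d component%s, %d wavelengths>\n",
    toupper(x$method), x$n_components,
    if (x$n_components == 1L) "" else "s", length(x$coefficients)
  ))
  invisible(x)
}

check_xy <- function(Xm, y, k) {
  if (nrow(Xm) != length(y)) {
    stop("X and y are not row-aligned", call. = FALSE)
  }
  if (k < 1L) stop("n_components must be >= 1", call. = FALSE)
  if (k > min(nrow(Xm) - 1L, ncol(Xm))) {
    stop(sprintf(
      "n_components = %d exceeds min(n_samples - 1, n_wavelengths) = %d",
      k, min(nrow(Xm) - 1L, ncol(Xm))
    ), call. = FALSE)
  }
}

#' Fit a PLS1 calibration model (NIPALS)
#'
#' Sequential NIPALS latent variables on centered data: each component's
#' weight vector is the normalized covariance `X'y`, scores are `X w`, and
#' `X` and `y` are deflated by the rank-one score/loading outer product
#' before the next component. The returned coefficient vector
#' `b = W (P'W)^{-1} q` reproduces the latent-variable prediction exactly.
#'
#' @param X A [spectra_set()] or numeric matrix (scans in rows).
#' @param y Numeric reference values, one per scan.
#' @param k Number of latent components.
#' @return A `calibration_model` with weights `W`, x-loadings `P`,
#'   y-loadings `q` and scores `T` alongside the coefficient vector.
#' @export
fit_pls <- function(X, y, k) {
  Xm <- x_matrix(X)
  y <- as.numeric(y)
  k <- as.integer(k)
  check_xy(Xm, y, k)
  x_mean <- colMeans(Xm)
  y_mean <- mean(y)
  E <- sweep(Xm, 2L, x_mean)
  f <- y - y_mean
  p <- ncol(Xm)
  W <- matrix(0, p, k)
  P <- matrix(0, p, k)
  Tm <- matrix(0, nrow(Xm), k)
  q <- numeric(k)
  for (a in seq_len(k)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12 * (1 + sqrt(sum(f^2)))) {
      stop(sprintf(
        "X carries no remaining covariance with y at component %d; reduce k", a
      ), call. = FALSE)
    }
    w <- w / wn
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    if (tt < .Machine$double.eps * nrow(Xm)) {
      stop(sprintf("rank deficiency at component %d; reduce k", a),
        call. = FALSE
      )
    }
    p_a <- drop(crossprod(E, t_a)) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - q_a * t_a
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    q[a] <- q_a
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  new_calibration_model(
    "pls", k, x_mean, y_mean, b, x_wavelengths(X),
    extra = list(W = W, P = P, q = q, scores = Tm, x_residual = E)
  )
}

#' Fit a principal component regression model
#'
#' Regresses centered `y` on the scores of the first `k` principal
#' components of centered `X` (components ordered by decreasing explained
#' variance). Sign convention: each loading vector is flipped so its
#' largest-magnitude element is positive, making fits reproducible.
#'
#' @inheritParams fit_pls
#' @return A `calibration_model` with loadings `V`, singular values `d`
#'   and scores `T`.
#' @export
fit_pcr <- function(X, y, k) {
  Xm <- x_matrix(X)
  y <- as.numeric(y)
  k <- as.integer(k)
  check_xy(Xm, y, k)
  x_mean <- colMeans(Xm)
  y_mean <- mean(y)
  E <- sweep(Xm, 2L, x_mean)
  sv <- svd(E, nu = k, nv = k)
  if (sv$d[k] < 1e-10 * sv$d[1L]) {
    stop(sprintf("k = %d exceeds the numerical rank of X", k), call. = FALSE)
  }
  V <- sv$v
  U <- sv$u
  for (a in seq_len(k)) { # deterministic sign
    j <- which.max(abs(V[, a]))
    if (V[j, a] < 0) {
      V[, a] <- -V[, a]
      U[, a] <- -U[, a]
    }
  }
  scores <- U %*% diag(sv$d[seq_len(k)], k, k)
  beta <- drop(crossprod(U[, seq_len(k), drop = FALSE], y - y_mean)) /
    sv$d[seq_len(k)]
  b <- drop(V[, seq_len(k), drop = FALSE] %*% beta)
  new_calibration_model(
    "pcr", k, x_mean, y_mean, b, x_wavelengths(X),
    extra = list(V = V, d = sv$d[seq_len(k)], scores = scores, beta = beta)
  )
}

#' Predict nutrient values from a calibration model
#'
#' `yhat = (X - x_mean) b + y_mean`. When both the model and `X` carry a
#' wavelength grid, the grids must match.
#'
#' @param object A `calibration_model`.
#' @param X A [spectra_set()] or matrix on the model's wavelength grid.
#' @param ... Unused.
#' @return Numeric vector of predicted values (percent).
#' @export
predict.calibration_model <- function(object, X, ...) {
  wl <- x_wavelengths(X)
  if (!is.null(wl) && !is.null(object$wavelengths)) {
    if (length(wl) != length(object$wavelengths) ||
      max(abs(wl - object$wavelengths)) > 1e-9) {
      stop("wavelength grid of X does not match the model's grid",
        call. = FALSE
      )
    }
  }
  Xm <- x_matrix(X)
  if (ncol(Xm) != length(object$coefficients)) {
    stop("X has the wrong number of wavelengths for this model", call. = FALSE)
  }
  drop(sweep(Xm, 2L, object$x_mean) %*% object$coefficients) + object$y_mean
}

#' Train/holdout split specification
#'
#' The random holdout (default 20 samples) is the prediction set on which
#' RMSEP/SEP/RPD are computed; cross-validation statistics (RMSECV/SECV)
#' come from k-fold or leave-one-out CV on the remaining calibration set.
#'
#' @param n_holdout Number of samples held out for prediction.
#' @param seed Integer seed for the split (and fold assignment); required.
#' @param cv `"k_fold"` or `"leave_one_out"`.
#' @param n_folds Folds for k-fold CV (default 10).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(n_holdout = 20L, seed,
                       cv = c("k_fold", "leave_one_out"), n_folds = 10L) {
  if (missing(seed)) stop("split_spec requires an explicit seed", call. = FALSE)
  cv <- match.arg(cv)
  if (n_holdout < 1L) stop("n_holdout must be >= 1", call. = FALSE)
  structure(
    list(
      n_holdout = as.integer(n_holdout), seed = as.integer(seed),
      cv = cv, n_folds = as.integer(n_folds)
    ),
    class = "split_spec"
  )
}

rmse <- function(r) sqrt(mean(r^2))
# bias-corrected standard error: spread of residuals about their mean, n-1
se_resid <- function(r) sqrt(sum((r - mean(r))^2) / (length(r) - 1L))
r_squared <- function(obs, pred) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    return(0)
  }
  stats::cor(obs, pred)^2
}

cv_predictions <- function(Xm, y, k, fitter, folds) {
  pred <- numeric(length(y))
  for (f in unique(folds)) {
    test <- folds == f
    m <- fitter(Xm[!test, , drop = FALSE], y[!test], k)
    pred[test] <- predict(m, Xm[test, , drop = FALSE])
  }
  pred
}

#' Validate a calibration: the full error-metric suite
#'
#' Splits the data into a calibration set and a random holdout prediction
#' set, fits the model on the calibration set, and reports root mean
#' square errors (divisor n), bias-corrected standard errors (residual
#' spread about its mean, divisor n-1) and squared correlations for
#' calibration (RMSEC/SEC/R2C), cross-validation on the calibration set
#' (RMSECV/SECV/R2CV) and holdout prediction (RMSEP/SEP/R2P), plus
#' `RPD = sd(holdout reference values) / SEP`.
#'
#' @param X A [spectra_set()] or matrix, one row per sample.
#' @param y Reference values aligned with the rows of `X`.
#' @param method `"pls"` or `"pcr"`.
#' @param k Number of components.
#' @param split A [split_spec()].
#' @return A `validation_report`: one-row data.frame with columns
#'   `method`, `k`, `rmsec`, `sec`, `r2c`, `rmsecv`, `secv`, `r2cv`,
#'   `rmsep`, `sep`, `r2p`, `rpd`, `n_cal`, `n_val`, and the fitted model
#'   in attribute `"model"`.
#' @export
validate <- function(X, y, method = c("pls", "pcr"), k, split) {
  method <- match.arg(method)
  stopifnot(inherits(split, "split_spec"))
  Xm <- x_matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (split$n_holdout >= n - 1L) {
    stop("holdout leaves too few calibration samples", call. = FALSE)
  }
  if (split$n_holdout < 2L) {
    stop("holdout must contain >= 2 samples for sd", call. = FALSE)
  }
  fitter <- if (method == "pls") fit_pls else fit_pcr
  set.seed(split$seed)
  hold <- sample.int(n, split$n_holdout)
  cal <- setdiff(seq_len(n), hold)
  n_cal <- length(cal)
  folds <- if (split$cv == "leave_one_out") {
    seq_len(n_cal)
  } else {
    sample(rep(seq_len(min(split$n_folds, n_cal)), length.out = n_cal))
  }
  model <- fitter(Xm[cal, , drop = FALSE], y[cal], k)
  pred_c <- predict(model, Xm[cal, , drop = FALSE])
  pred_cv <- cv_predictions(Xm[cal, , drop = FALSE], y[cal], k, fitter, folds)
  pred_p <- predict(model, Xm[hold, , drop = FALSE])
  rc <- y[cal] - pred_c
  rcv <- y[cal] - pred_cv
  rp <- y[hold] - pred_p
  sep <- se_resid(rp)
  rep <- data.frame(
    method = method, k = k,
    rmsec = rmse(rc), sec = se_resid(rc), r2c = r_squared(y[cal], pred_c),
    rmsecv = rmse(rcv), secv = se_resid(rcv), r2cv = r_squared(y[cal], pred_cv),
    rmsep = rmse(rp), sep = sep, r2p = r_squared(y[hold], pred_p),
    rpd = stats::sd(y[hold]) / sep,
    n_cal = n_cal, n_val = split$n_holdout
  )
  attr(rep, "model") <- model
  attr(rep, "holdout") <- hold
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' Choose the number of components by cross-validated error
#'
#' Computes RMSECV on the calibration subset for `k = 1 .. k_max` and
#' returns the minimizer; ties (within `1e-12` relative) break toward the
#' smaller, more parsimonious `k`.
#'
#' @inheritParams validate
#' @param k_max Largest number of components to try.
#' @return A list with `k` (chosen), and `rmsecv` (vector over k).
#' @export
select_components <- function(X, y, method = c("pls", "pcr"), split,
                              k_max = 10L) {
  method <- match.arg(method)
  stopifnot(inherits(split, "split_spec"))
  Xm <- x_matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  fitter <- if (method == "pls") fit_pls else fit_pcr
  set.seed(split$seed)
  hold <- sample.int(n, split$n_holdout)
  cal <- setdiff(seq_len(n), hold)
  n_cal <- length(cal)
  k_max <- min(k_max, n_cal - ceiling(n_cal / max(2L, split$n_folds)) - 1L,
    ncol(Xm))
  folds <- if (split$cv == "leave_one_out") {
    seq_len(n_cal)
  } else {
    sample(rep(seq_len(min(split$n_folds, n_cal)), length.out = n_cal))
  }
  rmsecv <- vapply(seq_len(k_max), function(k) {
    pred <- try(
      cv_predictions(Xm[cal, , drop = FALSE], y[cal], k, fitter, folds),
      silent = TRUE
    )
    if (inherits(pred, "try-error")) NA_real_ else rmse(y[cal] - pred)
  }, numeric(1L))
  ok <- which(!is.na(rmsecv))
  best <- min(rmsecv[ok])
  k <- ok[which(rmsecv[ok] <= best * (1 + 1e-12))[1L]]
  list(k = k, rmsecv = rmsecv)
}

#' Classify an RPD value
#'
#' Qualitative banding of the residual predictive deviation: `>= 3`
#' excellent, `[2, 3)` very reliable, `[1.5, 2)` limited, `< 1.5`
#' unreliable. Thresholds are configurable (published bandings vary and
#' sometimes overlap as printed).
#'
#' @param rpd Non-negative RPD value(s).
#' @param thresholds Increasing numeric vector `c(unreliable, limited,
#'   very_reliable)` giving the lower edges of the limited, very reliable
#'   and excellent bands.
#' @return Character vector of labels.
#' @export
classify_rpd <- function(rpd, thresholds = c(1.5, 2, 3)) {
  if (any(rpd < 0)) stop("RPD cannot be negative", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE) || length(thresholds) != 3L) {
    stop("thresholds must be three increasing values", call. = FALSE)
  }
  labs <- c("unreliable", "limited", "very reliable", "excellent")
  labs[findInterval(rpd, thresholds) + 1L]
}
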