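#' Estimate a regularized time-derivative of a single sweep
#'
#' Applies Phillips-Tikhonov regularization to estimate the first or second
#' time-derivative of a uniformly sampled noisy sweep. The estimate is the
#' minimizer of `||y - G u||^2 + gamma ||F u||^2`, computed through the SVD
#' of `H = G F^-1`: with `xi = t(U) %*% y` and `n_i = d_i xi_i /
#' (d_i^2 + gamma)`, the derivative is `u_hat = F^-1 V n` (the triangular
#' system `F u = V n` is solved directly, never by forming `F^-1`). Unless
#' supplied, `gamma` is selected by the discrepancy criterion
#' ([select_gamma()]). By-products are the regularized (smoothed) sweep
#' `G u_hat` and the normalized residuals `(y - G u_hat) / sigma`, which are
#' approximately white with unit variance when the noise model and `gamma`
#' are adequate.
#'
#' @param data A data frame with a `time` column (ms, uniform grid) and an
#'   `amplitude` column (mV) holding one sweep.
#' @param order Derivative order, 1 or 2.
#' @param sigma Noise standard deviation in mV, or `NULL` if `noise` is
#'   given.
#' @param noise Optionally a noise model from [estimate_sigma()].
#' @param gamma Fix the regularization parameter instead of selecting it by
#'   the discrepancy criterion.
#' @param ops Optionally precomputed [build_operators()] output matching the
#'   sweep; by default operators are built (and cached) for the sweep's
#'   `(N, order, dt)`.
#' @param rel_tol Relative tolerance passed to [select_gamma()].
#'
#' @return An object of class `lfp_estimate`: a list with `time`, `y`,
#'   `u_hat` (mV/ms or mV/ms^2), `smoothed` (mV), `residuals_norm`, `xi`,
#'   `gamma`, `wrss`, `sigma`, `order`, `n`, `dt`. Use [tidy()] for a
#'   per-sample tibble and [glance()] for a one-row fit summary.
#'
#' @examples
#' t <- seq(0, 30, by = 0.6)
#' y <- exp(-(t - 12)^2 / 18) + rnorm(length(t), sd = 0.05)
#' est <- estimate_derivative(data.frame(time = t, amplitude = y), sigma = 0.05)
#' glance(est)
#' @export
estimate_derivative <- function(data, order = 1, sigma = NULL, noise = NULL,
                                gamma = NULL, ops = NULL, rel_tol = 1e-3) {
  sw <- as_sweep(data)
  if (is.null(sigma)) {
    if (is.null(noise)) {
      abort("Supply `sigma` or a `noise` model from estimate_sigma().",
            class = "lfp_error_domain")
    }
    sigma <- noise$sigma
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    abort("`sigma` must be a single positive number (mV).",
          class = "lfp_error_domain")
  }
  if (is.null(ops)) {
    ops <- build_operators(sw$n, order, sw$dt)
  }
  if (ops$n != sw$n) {
    abort(sprintf("Operators are sized for N = %d but the sweep has N = %d.",
                  ops$n, sw$n), class = "lfp_error_sizing")
  }

  y <- sw$values
  xi <- drop(crossprod(ops$U, y))
  if (is.null(gamma)) {
    sel <- select_gamma(xi, ops$d, sigma, sw$n, rel_tol = rel_tol)
    gamma <- sel$gamma
    wrss <- sel$wrss
  } else {
    wrss <- wrss_at(gamma, xi, ops$d)
  }

  nvec <- ops$d * xi / (ops$d^2 + gamma)
  u_hat <- drop(forwardsolve(ops$F, ops$V %*% nvec))
  smoothed <- drop(ops$G %*% u_hat)

  structure(
    list(
      time = sw$time, y = y, u_hat = u_hat, smoothed = smoothed,
      residuals_norm = (y - smoothed) / sigma, xi = xi,
      gamma = gamma, wrss = wrss, sigma = sigma,
      order = ops$order, n = sw$n, dt = sw$dt
    ),
    class = "lfp_estimate"
  )
}

#' @export
print.lfp_estimate <- function(x, ...) {
  cat(sprintf(
    "<lfp_estimate> order %d, N = %d, dt = %g ms\n  gamma = %.4g, WRSS = %.4g (target N*sigma^2 = %.4g)\n",
    x$order, x$n, x$dt, x$gamma, x$wrss, x$n * x$sigma^2
  ))
  invisible(x)
}

#' Tidy a regularized derivative estimate
#'
#' @param x An `lfp_estimate`.
#' @param ... Unused.
#' @return A tibble with one row per sample: `time`, `amplitude` (raw),
#'   `smoothed`, `derivative`, `residual_norm`.
#' @method tidy lfp_estimate
#' @export
tidy.lfp_estimate <- function(x, ...) {
  tibble(
    time = x$time, amplitude = x$y, smoothed = x$smoothed,
    derivative = x$u_hat, residual_norm = x$residuals_norm
  )
}

#' Summarize a regularized derivative estimate
#'
#' @param x An `lfp_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: `order`, `n`, `dt`, `gamma`, `wrss`,
#'   `discrepancy_target`, `sigma`.
#' @method glance lfp_estimate
#' @export
glance.lfp_estimate <- function(x, ...) {
  tibble(
    order = x$order, n = x$n, dt = x$dt, gamma = x$gamma, wrss = x$wrss,
    discrepancy_target = x$n * x$sigma^2, sigma = x$sigma
  )
}

#' Estimate the noise standard deviation from a baseline segment
#'
#' Computes the sample standard deviation of the pre-stimulus baseline,
#' after subtracting the baseline mean (no slope removal). The estimate is
#' intended to be computed once and reused for all sweeps of a session. If
#' the baseline is (numerically) constant the estimate is floored at
#' `1e-9 * max(|amplitude|)` with a warning, since the discrepancy criterion
#' has no meaningful root on noiseless data.
#'
#' @param data A data frame with `time` and `amplitude` columns (one sweep).
#' @param baseline_window Length-2 numeric, the `[start, end)` interval in
#'   ms used as baseline; must contain at least 8 samples.
#' @param detrend Either `"mean"` (default: subtract the baseline mean) or
#'   `"none"`.
#'
#' @return A list of class `lfp_noise` with `sigma` (mV), `source`
#'   (`"estimated"`), `baseline_window`, `n_baseline` and `degenerate`
#'   (`TRUE` when the floor was applied).
#' @export
estimate_sigma <- function(data, baseline_window, detrend = c("mean", "none")) {
  detrend <- match.arg(detrend)
  sw <- as_sweep(data)
  if (!is.numeric(baseline_window) || length(baseline_window) != 2 ||
      baseline_window[1] >= baseline_window[2]) {
    abort("`baseline_window` must be an increasing length-2 interval (ms).",
          class = "lfp_error_window")
  }
  idx <- which(sw$time >= baseline_window[1] & sw$time < baseline_window[2])
  if (length(idx) < 8) {
    abort(sprintf(
      "Baseline window [%g, %g) ms contains %d samples; at least 8 required.",
      baseline_window[1], baseline_window[2], length(idx)),
      class = "lfp_error_window")
  }
  seg <- sw$values[idx]
  if (detrend == "mean") seg <- seg - mean(seg)
  sigma <- sd(seg)
  floor_val <- 1e-9 * max(abs(sw$values))
  degenerate <- FALSE
  if (!is.finite(sigma) || sigma < floor_val) {
    warn(sprintf(
      "Baseline segment is (nearly) noiseless; flooring sigma at %.3g mV.",
      floor_val), class = "lfp_warning_degenerate_noise")
    sigma <- floor_val
    degenerate <- TRUE
  }
  structure(
    list(sigma = sigma, source = "estimated",
         baseline_window = baseline_window, n_baseline = length(idx),
         degenerate = degenerate),
    class = "lfp_noise"
  )
}

#' Wrap a known noise standard deviation as a noise model
#'
#' @param sigma Noise standard deviation (mV), positive.
#' @return A list of class `lfp_noise` with `source = "literal"`.
#' @export
noise_model <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    abort("`sigma` must be a single positive number.", class = "lfp_error_domain")
  }
  structure(list(sigma = sigma, source = "literal", baseline_window = NULL,
                 degenerate = FALSE), class = "lfp_noise")
}

#' @export
print.lfp_noise <- function(x, ...) {
  cat(sprintf("<lfp_noise> sigma = %.4g mV (%s)\n", x$sigma, x$source))
  invisible(x)
}

# Validate a single-sweep data frame and return time/values/dt.
as_sweep <- function(data) {
  if (!is.data.frame(data) || !all(c("time", "amplitude") %in% names(data))) {
    abort("`data` must be a data frame with `time` and `amplitude` columns.",
          class = "lfp_error_domain")
  }
  if ("sweep" %in% names(data) && length(unique(data$sweep)) > 1) {
    abort("`data` contains multiple sweeps; supply one sweep at a time here.",
          class = "lfp_error_domain")
  }
  time <- as.numeric(data$time)
  values <- as.numeric(data$amplitude)
  n <- length(values)
  if (n < 8) {
    abort(sprintf("Sweep has %d samples; at least 8 required.", n),
          class = "lfp_error_sizing")
  }
  if (any(!is.finite(values)) || any(!is.finite(time))) {
    abort("Sweep contains non-finite values.", class = "lfp_error_domain")
  }
  dts <- diff(time)
  dt <- stats::median(dts)
  if (dt <= 0 || any(abs(dts - dt) > 1e-6 * dt)) {
    abort("Sweep time grid must be strictly increasing and uniform.",
          class = "lfp_error_format")
  }
  list(time = time, values = values, n = n, dt = dt, t0 = time[1])
}
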