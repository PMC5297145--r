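#' Build the regularization operators for derivative estimation
#'
#' Constructs the lower-triangular Toeplitz integration operator `G`, the
#' second-difference penalty operator `F`, and the singular value
#' decomposition of `H = G F^-1` used by the fast discrepancy search. For a
#' uniformly sampled signal `y`, the measurement model is `y = G u + v`,
#' where `u` holds the samples of the first (`order = 1`) or second
#' (`order = 2`) time-derivative and `v` is white measurement noise.
#'
#' The first column of `G` is all ones for `order = 1` (cumulative sum, i.e.
#' causal integration) and `1, 2, ..., N` for `order = 2` (double cumulative
#' sum), multiplied by `dt` and `dt^2` respectively so that `u` carries
#' physical units (mV/ms and mV/ms^2 for a signal in mV sampled in ms).
#' With `dt = 1` the operators reduce to their per-sample (unit) form.
#'
#' The SVD is the expensive O(N^3) step; it is computed once per
#' `(n_samples, order, dt)` configuration and cached for the session.
#'
#' @param n_samples Number of samples `N` (at least 8).
#' @param order Derivative order, 1 or 2.
#' @param dt Sampling interval in ms (positive).
#' @param cache Reuse a previously computed decomposition for the same
#'   configuration (default `TRUE`).
#'
#' @return An object of class `reg_operators`: a list with elements `order`,
#'   `n`, `dt`, `dt_scale`, matrices `G`, `F`, `U`, `V` and the singular
#'   values `d` of `H = G F^-1` (so that `t(U) %*% H %*% V = diag(d)`).
#'
#' @examples
#' ops <- build_operators(16, order = 1, dt = 0.6)
#' max(abs(crossprod(ops$U) - diag(16)))  # orthonormal
#' @export
build_operators <- function(n_samples, order, dt = 1, cache = TRUE) {
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 8) {
    abort("`n_samples` must be a single number >= 8.", class = "lfp_error_sizing")
  }
  n <- as.integer(n_samples)
  if (!order %in% c(1, 2)) {
    abort("`order` must be 1 or 2.", class = "lfp_error_order")
  }
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    abort("`dt` must be a single positive number.", class = "lfp_error_domain")
  }

  key <- sprintf("%d_%d_%.17g", n, order, dt)
  if (cache && !is.null(.op_cache[[key]])) {
    return(.op_cache[[key]])
  }

  dt_scale <- if (order == 1) dt else dt^2
  first_col <- if (order == 1) rep(1, n) else seq_len(n)
  G <- matrix(0, n, n)
  for (j in seq_len(n)) {
    G[j:n, j] <- first_col[seq_len(n - j + 1)]
  }
  G <- G * dt_scale

  Fm <- diag(n)
  Fm[cbind(2:n, 1:(n - 1))] <- -2
  if (n > 2) Fm[cbind(3:n, 1:(n - 2))] <- 1

  # H = G F^-1 without forming F^-1: solve t(F) t(H) = t(G)
  H <- t(backsolve(t(Fm), t(G)))
  s <- svd(H)

  ops <- structure(
    list(order = order, n = n, dt = dt, dt_scale = dt_scale,
         G = G, F = Fm, U = s$u, V = s$v, d = s$d),
    class = "reg_operators"
  )
  if (cache) .op_cache[[key]] <- ops
  ops
}

#' @export
print.reg_operators <- function(x, ...) {
  cat(sprintf(
    "<reg_operators> order %d, N = %d, dt = %g ms, d in [%.3g, %.3g]\n",
    x$order, x$n, x$dt, min(x$d), max(x$d)
  ))
  invisible(x)
}

#' Weighted residual sum of squares in the SVD basis
#'
#' Evaluates `WRSS(gamma) = sum_i (gamma * xi_i / (d_i^2 + gamma))^2`, the
#' weighted residual sum of squares of the regularized estimate expressed in
#' the singular basis, where `xi = t(U) %*% y` and `d` are the singular
#' values of `H = G F^-1`. `WRSS` is nondecreasing in `gamma`, which makes
#' the discrepancy criterion a one-dimensional root-finding problem that
#' costs O(N) per trial value of `gamma`.
#'
#' @param gamma Nonnegative regularization parameter.
#' @param xi Work vector `t(U) %*% y`.
#' @param d Singular values, same length as `xi`.
#' @return The scalar WRSS value.
#' @examples
#' wrss_at(1, xi = c(1, 1), d = c(1, 1))  # 0.5
#' @export
wrss_at <- function(gamma, xi, d) {
  if (!is.numeric(gamma) || length(gamma) != 1 || is.na(gamma) || gamma < 0) {
    abort("`gamma` must be a single nonnegative number.", class = "lfp_error_domain")
  }
  if (length(xi) != length(d)) {
    abort("`xi` and `d` must have the same length.", class = "lfp_error_sizing")
  }
  if (gamma == 0) {
    return(sum(xi[d == 0]^2))
  }
  sum((gamma * xi / (d^2 + gamma))^2)
}

#' Select the regularization parameter by the discrepancy criterion
#'
#' Finds the `gamma` at which the weighted residual sum of squares matches
#' its statistical expectation under the white-noise model,
#' `WRSS(gamma) = N * sigma^2`. Because `WRSS` is monotone in `gamma` the
#' root is unique; it is located by bisection on `log10(gamma)` (bracketed
#' within `10^log10_range`, expanded if needed), a derivative-free search
#' that is robust to the scale of the singular values.
#'
#' @param xi Work vector `t(U) %*% y`.
#' @param d Singular values of `H`.
#' @param sigma Noise standard deviation (mV), positive.
#' @param n_samples Number of samples `N` of the sweep.
#' @param rel_tol Relative tolerance on the discrepancy match:
#'   `|WRSS(gamma) - N sigma^2| <= rel_tol * N sigma^2` (default `1e-3`).
#' @param log10_range Initial log10 bracket for `gamma` (default `c(-12, 12)`).
#' @param max_iter Maximum bisection iterations (default 200).
#'
#' @return A list with `gamma`, `wrss`, `target` (`N sigma^2`) and
#'   `iterations`.
#'
#' @section Errors: if the target exceeds the supremum of `WRSS`
#'   (`sum(xi^2)`, the limit as `gamma` grows), no root exists — typically a
#'   noiseless signal or an overstated `sigma` — and an error of class
#'   `lfp_error_noroot` is raised carrying both `target` and `supremum`, so
#'   callers can fall back to a configured `gamma` bound.
#' @export
select_gamma <- function(xi, d, sigma, n_samples, rel_tol = 1e-3,
                         log10_range = c(-12, 12), max_iter = 200) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    abort("`sigma` must be a single positive number.", class = "lfp_error_domain")
  }
  target <- n_samples * sigma^2
  supremum <- sum(xi^2)
  if (target >= supremum) {
    abort(
      sprintf(paste0(
        "Discrepancy target N*sigma^2 = %.6g is not below the WRSS supremum ",
        "%.6g; no gamma satisfies the criterion (signal too clean or sigma ",
        "too large)."), target, supremum),
      class = "lfp_error_noroot", target = target, supremum = supremum
    )
  }

  f <- function(lg) wrss_at(10^lg, xi, d) - target
  lo <- log10_range[1]
  hi <- log10_range[2]
  while (f(lo) > 0 && lo > -30) lo <- lo - 6
  while (f(hi) < 0 && hi < 30) hi <- hi + 6
  if (f(lo) > 0 || f(hi) < 0) {
    abort("Failed to bracket the discrepancy root.",
          class = "lfp_error_noroot", target = target, supremum = supremum)
  }

  iter <- 0L
  mid <- (lo + hi) / 2
  repeat {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    val <- f(mid)
    if (abs(val) <= rel_tol * target || iter >= max_iter) break
    if (val < 0) lo <- mid else hi <- mid
  }
  gamma <- 10^mid
  list(gamma = gamma, wrss = wrss_at(gamma, xi, d), target = target,
       iterations = iter)
}
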