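#' Detection configuration
#'
#' Parameters governing windowing, downsampling and rule-based feature
#' detection. Defaults follow common practice for whisker-evoked LFPs in rat
#' barrel cortex: the analysis window runs from 5 ms (skipping the
#' electro-mechanical stimulation artifact) to 50 ms post-stimulus, and a
#' 50 kHz acquisition is decimated by 30 (to dt = 0.6 ms).
#'
#' @param window_start,window_end Analysis window in ms post-stimulus,
#'   half-open `[window_start, window_end)` (defaults 5 and 50).
#' @param downsample_factor Keep every n-th sample of the windowed segment
#'   (default 30, no anti-alias filter).
#' @param onset_position Relative position `p` of the onset between the
#'   first maximum and the negative peak, in `[0, 1]`; `p = 0` identifies
#'   the onset with the first maximum (default 0).
#' @param min_distance Minimum separation in ms required between the first
#'   maximum and the negative peak (default 5), guarding against picking a
#'   local minimum instead of the global one.
#' @param rel_tol Relative tolerance for the discrepancy criterion.
#' @param gamma_fallback Optional `gamma` to use when the discrepancy
#'   criterion has no root for a sweep (default `NULL`: such sweeps fail).
#'
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(window_start = 5, window_end = 50,
                             downsample_factor = 30, onset_position = 0,
                             min_distance = 5, rel_tol = 1e-3,
                             gamma_fallback = NULL) {
  if (window_start < 0 || window_start >= window_end) {
    abort("Need 0 <= window_start < window_end.", class = "lfp_error_config")
  }
  if (downsample_factor < 1 || downsample_factor != round(downsample_factor)) {
    abort("`downsample_factor` must be a positive integer.",
          class = "lfp_error_config")
  }
  if (onset_position < 0 || onset_position > 1) {
    abort("`onset_position` must lie in [0, 1].", class = "lfp_error_config")
  }
  if (min_distance < 0 || min_distance >= (window_end - window_start)) {
    abort("`min_distance` must be >= 0 and smaller than the analysis window.",
          class = "lfp_error_config")
  }
  structure(
    list(window_start = window_start, window_end = window_end,
         downsample_factor = as.integer(downsample_factor),
         onset_position = onset_position, min_distance = min_distance,
         rel_tol = rel_tol, gamma_fallback = gamma_fallback),
    class = "detection_config"
  )
}

#' @export
print.detection_config <- function(x, ...) {
  cat(sprintf(
    "<detection_config> window [%g, %g) ms, decimate by %d, onset p = %g, min distance %g ms\n",
    x$window_start, x$window_end, x$downsample_factor, x$onset_position,
    x$min_distance
  ))
  invisible(x)
}

#' Window and decimate sweeps
#'
#' Restricts each sweep to the analysis window `[window_start, window_end)`
#' (the first kept sample is the first with `time >= window_start`) and
#' decimates by keeping every n-th sample. No anti-alias filter is applied:
#' the regularization step downstream performs the smoothing. The absolute
#' time base is preserved.
#'
#' @param data A data frame with `time` and `amplitude` columns, optionally
#'   a `sweep` column for multiple sweeps.
#' @param config A [detection_config()].
#' @return A tibble of the same shape restricted to the decimated window.
#' @export
preprocess <- function(data, config = detection_config()) {
  stopifnot(is.data.frame(data))
  one <- function(df) {
    keep <- which(df$time >= config$window_start & df$time < config$window_end)
    if (length(keep) == 0) {
      abort("Analysis window contains no samples.", class = "lfp_error_window")
    }
    idx <- keep[seq(1, length(keep), by = config$downsample_factor)]
    if (length(idx) == 0) {
      abort("Analysis window is empty after decimation.",
            class = "lfp_error_window")
    }
    df[idx, , drop = FALSE]
  }
  if ("sweep" %in% names(data)) {
    out <- data |>
      dplyr::group_by(.data$sweep) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  } else {
    out <- one(data)
  }
  as_tibble(out)
}

#' Locate the first maximum and the main negative peak
#'
#' Candidate maxima are grid points where the estimated first derivative
#' crosses zero from positive to negative; candidate minima are crossings
#' from negative to positive (a sign change is required, not merely a zero
#' value). The crossing is assigned to the later of the two bracketing
#' samples, then refined to the grid point with the extremal smoothed value
#' within one sample. The negative peak is the candidate minimum with the
#' most negative smoothed value (global-minimum rule); the first maximum is
#' the earliest candidate maximum preceding the peak by at least
#' `min_distance`.
#'
#' @param data A data frame with columns `time`, `smoothed` and `d1` on a
#'   common grid (see [extract_features()] for how these are produced).
#' @param config A [detection_config()].
#' @return A one-row tibble: `t_max`, `A_max`, `t_peak`, `A_peak`
#'   (magnitude of the deflection), `A_peak_signed`, plus grid indices
#'   `i_max`, `i_peak`.
#' @export
find_extrema <- function(data, config = detection_config()) {
  stopifnot(is.data.frame(data),
            all(c("time", "smoothed", "d1") %in% names(data)))
  time <- data$time
  sm <- data$smoothed
  d1 <- data$d1
  n <- length(d1)

  refine <- function(i, fun) {
    cand <- max(1L, i - 1L):min(n, i + 1L)
    cand[fun(sm[cand])]
  }

  br <- seq_len(n - 1)
  down <- which(d1[br] > 0 & d1[br + 1] < 0) + 1L   # + to -: maxima
  up <- which(d1[br] < 0 & d1[br + 1] > 0) + 1L     # - to +: minima
  if (length(up) == 0) {
    abort("No negative-to-positive zero crossing of the first derivative: no minimum candidate.",
          class = "lfp_error_detection", constraint = "no_minimum")
  }
  if (length(down) == 0) {
    abort("No positive-to-negative zero crossing of the first derivative: no maximum candidate.",
          class = "lfp_error_detection", constraint = "no_maximum")
  }

  min_idx <- vapply(up, refine, integer(1), fun = which.min)
  i_peak <- min_idx[which.min(sm[min_idx])]

  max_idx <- vapply(down, refine, integer(1), fun = which.max)
  ok <- max_idx < i_peak & (time[i_peak] - time[max_idx]) >= config$min_distance
  if (!any(ok)) {
    abort(sprintf(
      "No maximum candidate precedes the negative peak at %g ms by at least min_distance = %g ms.",
      time[i_peak], config$min_distance),
      class = "lfp_error_detection", constraint = "min_distance")
  }
  i_max <- min(max_idx[ok])

  tibble(
    t_max = time[i_max], A_max = sm[i_max],
    t_peak = time[i_peak], A_peak = abs(sm[i_peak]),
    A_peak_signed = sm[i_peak], i_max = i_max, i_peak = i_peak
  )
}

#' Locate the response onset between the first maximum and the peak
#'
#' The onset is placed at the relative position `p` between the first
#' maximum and the negative peak, `t_onset = t_max + p (t_peak - t_max)`,
#' snapped to the nearest grid point; its amplitude is read from the
#' smoothed signal there. With `p = 0` the onset coincides with the first
#' maximum.
#'
#' @param data A data frame with columns `time` and `smoothed`.
#' @param t_max,t_peak Latencies (ms) from [find_extrema()].
#' @param p Onset position in `[0, 1]`.
#' @return A one-row tibble: `t_onset`, `A_onset`, `i_onset`.
#' @export
locate_onset <- function(data, t_max, t_peak, p = 0) {
  stopifnot(t_max < t_peak, p >= 0, p <= 1)
  target <- t_max + p * (t_peak - t_max)
  i <- which.min(abs(data$time - target))
  tibble(t_onset = data$time[i], A_onset = data$smoothed[i], i_onset = i)
}

#' Locate the inflection point between the first maximum and the peak
#'
#' Finds where the estimated second derivative crosses zero strictly inside
#' `(t_max, t_peak)`; a sign change is verified in a neighborhood of two
#' samples on either side of the crossing. If several verified crossings
#' exist, the one with the largest first-derivative magnitude (steepest
#' descent) is returned. The reported value is the first derivative at the
#' inflection point, which measures the descent rate between onset and
#' peak.
#'
#' @param data A data frame with columns `time`, `d1` and `d2`.
#' @param t_max,t_peak Latencies (ms) bounding the search interval.
#' @return A one-row tibble: `t_inflection`, `d1_inflection`,
#'   `i_inflection`.
#' @section Errors: if no sign-changing zero exists in the interval, an
#'   error of class `lfp_error_inflection` is raised; [extract_features()]
#'   converts this into missing inflection fields rather than a failed
#'   sweep.
#' @export
locate_inflection <- function(data, t_max, t_peak) {
  stopifnot(t_max < t_peak)
  time <- data$time
  d1 <- data$d1
  d2 <- data$d2
  n <- length(d2)

  br <- which(time[-n] > t_max & time[-1] < t_peak)
  cross <- br[d2[br] * d2[br + 1] < 0]
  verified <- cross[vapply(cross, function(i) {
    left <- d2[max(1L, i - 2L):i]
    right <- d2[(i + 1L):min(n, i + 3L)]
    all(sign(left) == sign(d2[i])) && all(sign(right) == sign(d2[i + 1L]))
  }, logical(1))]
  if (length(verified) == 0) {
    abort("No sign-changing zero of the second derivative between the first maximum and the negative peak.",
          class = "lfp_error_inflection")
  }
  # The causal second-difference operator localizes d2 about one sample
  # early, so the earlier sample of the sign-change bracket is the less
  # biased grid estimate of the crossing. Steepest-descent tie-break.
  idx <- verified
  i <- idx[which.max(abs(d1[idx]))]
  tibble(t_inflection = time[i], d1_inflection = d1[i], i_inflection = i)
}

#' Extract LFP features from one or many sweeps
#'
#' Full pipeline for each sweep: window and decimate ([preprocess()]),
#' estimate the regularized first and second time-derivatives
#' ([estimate_derivative()], each with its own discrepancy-selected
#' `gamma`), then detect the first maximum and negative peak
#' ([find_extrema()]), the onset ([locate_onset()]) and the inflection
#' point ([locate_inflection()]). Amplitudes are read from the regularized
#' (smoothed) sweep of the first-derivative fit. Detection failures do not
#' abort the batch: the affected sweep is reported with a non-`"ok"`
#' status and empty feature cells.
#'
#' @param data A data frame with `time` and `amplitude` columns and
#'   optionally a `sweep` column (multiple sweeps).
#' @param config A [detection_config()].
#' @param sigma Noise standard deviation (mV) shared by all sweeps, or
#'   `NULL` if `noise` is given.
#' @param noise Optionally an `lfp_noise` model.
#' @param diagnostics If `TRUE`, attach a list of per-sweep diagnostic
#'   tibbles (`time`, `amplitude`, `smoothed`, `d1`, `d2`,
#'   `residual_norm`) as attribute `"diagnostics"` for plotting.
#'
#' @return A tibble of class `lfp_features` with one row per sweep:
#'   `sweep`, `t_max`, `A_max`, `t_onset`, `A_onset`, `t_peak`, `A_peak`
#'   (deflection magnitude, mV), `d1_inflection` (mV/ms), `latency_param`
#'   (`t_peak - t_onset`, ms), `status` (`"ok"`, `"no_inflection"` or
#'   `"failed"`), plus `t_inflection`, `A_peak_signed`, `gamma_d1`,
#'   `gamma_d2` and `detail` (failure message).
#' @export
extract_features <- function(data, config = detection_config(), sigma = NULL,
                             noise = NULL, diagnostics = FALSE) {
  if (is.null(sigma)) {
    if (is.null(noise)) {
      abort("Supply `sigma` or a `noise` model.", class = "lfp_error_domain")
    }
    sigma <- noise$sigma
  }
  stopifnot(is.data.frame(data))
  if (!"sweep" %in% names(data)) {
    data <- dplyr::mutate(data, sweep = 1L)
  }

  diag_list <- list()
  rows <- data |>
    dplyr::group_by(.data$sweep) |>
    dplyr::group_map(function(df, key) {
      res <- extract_one(df, config, sigma, diagnostics)
      if (diagnostics && !is.null(res$diag)) {
        diag_list[[as.character(key$sweep)]] <<- res$diag
      }
      dplyr::bind_cols(tibble(sweep = key$sweep), res$row)
    }) |>
    dplyr::bind_rows()

  out <- structure(rows, class = c("lfp_features", class(rows)))
  if (diagnostics) attr(out, "diagnostics") <- diag_list
  out
}

na_feature_row <- function(status, detail) {
  tibble(
    t_max = NA_real_, A_max = NA_real_, t_onset = NA_real_,
    A_onset = NA_real_, t_peak = NA_real_, A_peak = NA_real_,
    d1_inflection = NA_real_, latency_param = NA_real_, status = status,
    t_inflection = NA_real_, A_peak_signed = NA_real_,
    gamma_d1 = NA_real_, gamma_d2 = NA_real_, detail = detail
  )
}

extract_one <- function(df, config, sigma, diagnostics) {
  row <- tryCatch({
    pre <- preprocess(df, config)
    est1 <- with_gamma_fallback(pre, 1, sigma, config)
    est2 <- with_gamma_fallback(pre, 2, sigma, config)
    grid <- tibble(time = est1$time, smoothed = est1$smoothed,
                   d1 = est1$u_hat, d2 = est2$u_hat)

    ext <- find_extrema(grid, config)
    ons <- locate_onset(grid, ext$t_max, ext$t_peak, config$onset_position)
    infl <- tryCatch(
      locate_inflection(grid, ext$t_max, ext$t_peak),
      lfp_error_inflection = function(e) {
        tibble(t_inflection = NA_real_, d1_inflection = NA_real_,
               i_inflection = NA_integer_)
      }
    )
    status <- if (is.na(infl$t_inflection)) "no_inflection" else "ok"

    out <- tibble(
      t_max = ext$t_max, A_max = ext$A_max,
      t_onset = ons$t_onset, A_onset = ons$A_onset,
      t_peak = ext$t_peak, A_peak = ext$A_peak,
      d1_inflection = infl$d1_inflection,
      latency_param = ext$t_peak - ons$t_onset,
      status = status, t_inflection = infl$t_inflection,
      A_peak_signed = ext$A_peak_signed,
      gamma_d1 = est1$gamma, gamma_d2 = est2$gamma, detail = NA_character_
    )
    attr(out, "diag") <- if (diagnostics) {
      tibble(time = est1$time, amplitude = est1$y, smoothed = est1$smoothed,
             d1 = est1$u_hat, d2 = est2$u_hat,
             residual_norm = est1$residuals_norm)
    }
    out
  },
  lfp_error_detection = function(e) na_feature_row("failed", conditionMessage(e)),
  lfp_error_noroot = function(e) na_feature_row("failed", conditionMessage(e)),
  lfp_error_window = function(e) na_feature_row("failed", conditionMessage(e)),
  lfp_error_sizing = function(e) na_feature_row("failed", conditionMessage(e))
  )
  list(row = row, diag = attr(row, "diag"))
}

with_gamma_fallback <- function(pre, order, sigma, config) {
  tryCatch(
    estimate_derivative(pre, order = order, sigma = sigma,
                        rel_tol = config$rel_tol),
    lfp_error_noroot = function(e) {
      if (is.null(config$gamma_fallback)) rlang::cnd_signal(e)
      estimate_derivative(pre, order = order, sigma = sigma,
                          gamma = config$gamma_fallback)
    }
  )
}
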