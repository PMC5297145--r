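#' Plot a regularized derivative estimate
#'
#' Stacked panels of the raw sweep, the regularized (smoothed) sweep, the
#' estimated derivative and the normalized residuals, the standard visual
#' check that the discrepancy-selected smoothing is adequate (residuals
#' approximately white, mostly within +/- 1).
#'
#' @param object An `lfp_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lfp_estimate
#' @export
autoplot.lfp_estimate <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::pivot_longer(td, -"time", names_to = "panel",
                              values_to = "value")
  long$panel <- factor(long$panel,
                       levels = c("amplitude", "smoothed", "derivative",
                                  "residual_norm"),
                       labels = c("raw (mV)", "regularized (mV)",
                                  sprintf("derivative order %d", object$order),
                                  "normalized residuals"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~ .data$panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = sprintf("Regularized estimate (gamma = %.3g)",
                                  object$gamma)) +
    ggplot2::theme_minimal()
}

#' Plot detected features over a sweep
#'
#' Draws the regularized sweep with the detected first maximum, onset,
#' inflection point and negative peak marked, for one sweep of an
#' [extract_features()] run executed with `diagnostics = TRUE`.
#'
#' @param features An `lfp_features` tibble carrying diagnostics.
#' @param sweep Which sweep to plot (default: the first).
#' @return A ggplot object.
#' @export
plot_features <- function(features, sweep = NULL) {
  diags <- attr(features, "diagnostics")
  if (is.null(diags)) {
    abort("Re-run extract_features() with diagnostics = TRUE to plot.",
          class = "lfp_error_domain")
  }
  sweep <- sweep %||% features$sweep[1]
  dg <- diags[[as.character(sweep)]]
  row <- features[features$sweep == sweep, ]
  pts <- tibble(
    time = c(row$t_max, row$t_onset, row$t_inflection, row$t_peak),
    feature = factor(c("first maximum", "onset", "inflection",
                       "negative peak"),
                     levels = c("first maximum", "onset", "inflection",
                                "negative peak"))
  )
  pts <- pts[!is.na(pts$time), ]
  pts$amplitude <- dg$smoothed[match(pts$time, dg$time)]
  ggplot2::ggplot(dg, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$amplitude), colour = "grey60",
                       linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), linewidth = 0.5) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(y = .data$amplitude,
                                     colour = .data$feature), size = 2) +
    ggplot2::labs(x = "time (ms)", y = "LFP (mV)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Boxplots of Monte Carlo feature errors by SNR
#'
#' @param object An `lfp_error_table` from [run_monte_carlo()].
#' @param ... Unused.
#' @return A ggplot object with one panel per error index.
#' @method autoplot lfp_error_table
#' @export
autoplot.lfp_error_table <- function(object, ...) {
  errs <- attr(object, "sweep_errors")
  if (is.null(errs)) {
    abort("This error table carries no per-sweep records.",
          class = "lfp_error_domain")
  }
  long <- errs |>
    dplyr::filter(.data$status != "failed") |>
    dplyr::select("snr", "sweep", dplyr::starts_with("e_")) |>
    tidyr::pivot_longer(dplyr::starts_with("e_"), names_to = "index",
                        values_to = "error", names_prefix = "e_") |>
    dplyr::filter(!is.na(.data$error))
  long$snr_label <- factor(
    ifelse(is.infinite(long$snr), "noiseless", format(long$snr)),
    levels = unique(ifelse(is.infinite(errs$snr), "noiseless",
                           format(errs$snr))))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$snr_label, y = .data$error)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~ .data$index, scales = "free_y") +
    ggplot2::labs(x = "SNR", y = "error (estimated - true)") +
    ggplot2::theme_minimal()
}
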