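#' Monte Carlo study of feature-estimation error versus SNR
#'
#' For each SNR level, generates `n_sweeps` noisy realizations of the
#' noiseless template, runs the full detection pipeline on each, and
#' compares the detected features with the template's analytic ground
#' truth. Latency errors are reported in ms as `estimated - true`;
#' amplitude and derivative errors are normalized to the true value,
#' `(estimated - true) / true`, and are therefore signed. The noise
#' standard deviation handed to the detector is the true `sd_noise` of the
#' level (mirroring a baseline estimate made once for all sweeps); the
#' noiseless level uses the degenerate-noise floor.
#'
#' Reproducibility: one master `seed` spawns an independent child seed per
#' (level, sweep), so per-sweep results do not depend on `n_sweeps` or on
#' the ordering of levels.
#'
#' @param spec A [template_spec()] (default template).
#' @param snr_levels Numeric SNR levels; `Inf` denotes the noiseless case
#'   (default `c(Inf, 10, 5, 3)`).
#' @param n_sweeps Sweeps per level (default 100, minimum 2).
#' @param seed Master RNG seed.
#' @param config A [detection_config()].
#' @param max_fail_frac If more than this fraction of sweeps fails
#'   detection at a level (default 0.2), that level is aborted: its error
#'   cells are `NA` and a warning carries the failure diagnostics.
#'
#' @return A tibble of class `lfp_error_table`, one row per SNR level:
#'   `snr`, `n_ok`, `n_fail`, and `mean_` / `sd_` columns for the five
#'   error indices `t_max` (ms), `A_max` (normalized), `t_peak` (ms),
#'   `A_peak` (normalized), `d1_inflection` (normalized). The per-sweep
#'   error records are attached as attribute `"sweep_errors"` and the
#'   ground truth as attribute `"ground_truth"`.
#' @examples
#' \donttest{
#' tab <- run_monte_carlo(n_sweeps = 10, seed = 1)
#' tab
#' }
#' @export
run_monte_carlo <- function(spec = template_spec(),
                            snr_levels = c(Inf, 10, 5, 3),
                            n_sweeps = 100, seed = 1,
                            config = detection_config(),
                            max_fail_frac = 0.2) {
  stopifnot(n_sweeps >= 2, all(snr_levels > 0))
  tpl <- make_template(spec)
  gt <- tpl$ground_truth
  sigma_floor <- 1e-9 * max(abs(tpl$sweep$amplitude))

  level_tag <- function(snr) if (is.infinite(snr)) 0L else as.integer(round(snr * 64))

  per_sweep <- purrr::map(snr_levels, function(snr) {
    sd_noise <- if (is.infinite(snr)) 0 else tpl$sd_lfp / sqrt(snr)
    sigma <- max(sd_noise, sigma_floor)
    purrr::map(seq_len(n_sweeps), function(i) {
      child <- (as.numeric(seed) * 48271 + level_tag(snr) * 69621 +
                  i * 16807) %% 2147483647
      noisy <- withr::with_seed(as.integer(child), add_noise(tpl, snr))
      feat <- extract_features(noisy, config, sigma = sigma)
      dplyr::bind_cols(tibble(snr = snr, sweep = i), feat[, -1])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  errors <- per_sweep |>
    dplyr::mutate(
      e_t_max = .data$t_max - gt$t_max,
      e_A_max = (.data$A_max - gt$A_max) / gt$A_max,
      e_t_peak = .data$t_peak - gt$t_peak,
      e_A_peak = (.data$A_peak - gt$A_peak) / gt$A_peak,
      e_d1_inflection = (.data$d1_inflection - gt$d1_inflection) /
        gt$d1_inflection
    )

  summarize_level <- function(df, snr) {
    ok <- df$status != "failed"
    n_ok <- sum(ok)
    n_fail <- sum(!ok)
    if (n_fail > max_fail_frac * nrow(df)) {
      warn(sprintf(
        "SNR %s: %d of %d sweeps failed detection (%s); level aborted.",
        format(snr), n_fail, nrow(df),
        paste(unique(stats::na.omit(df$detail)), collapse = "; ")),
        class = "lfp_warning_level_aborted")
      agg <- rep(NA_real_, 10)
    } else {
      cols <- c("e_t_max", "e_A_max", "e_t_peak", "e_A_peak",
                "e_d1_inflection")
      vals <- df[ok, cols]
      agg <- unname(c(vapply(vals, mean, numeric(1), na.rm = TRUE),
                      vapply(vals, sd, numeric(1), na.rm = TRUE)))
    }
    tibble(
      snr = snr, n_ok = n_ok, n_fail = n_fail,
      mean_t_max = agg[1], mean_A_max = agg[2], mean_t_peak = agg[3],
      mean_A_peak = agg[4], mean_d1_inflection = agg[5],
      sd_t_max = agg[6], sd_A_max = agg[7], sd_t_peak = agg[8],
      sd_A_peak = agg[9], sd_d1_inflection = agg[10]
    )
  }

  tab <- errors |>
    dplyr::group_split(.data$snr) |>
    purrr::map(~ summarize_level(.x, .x$snr[1])) |>
    dplyr::bind_rows() |>
    dplyr::arrange(match(.data$snr, snr_levels))

  out <- structure(tab, class = c("lfp_error_table", class(tab)))
  attr(out, "sweep_errors") <- errors
  attr(out, "ground_truth") <- gt
  out
}

#' @export
print.lfp_error_table <- function(x, ...) {
  cat("Monte Carlo error indices (mean (sd) over successful sweeps)\n")
  fmt <- function(m, s) ifelse(is.na(m), "-", sprintf("%.3g (%.3g)", m, s))
  df <- data.frame(
    SNR = ifelse(is.infinite(x$snr), "noiseless", format(x$snr)),
    t_max_ms = fmt(x$mean_t_max, x$sd_t_max),
    A_max_norm = fmt(x$mean_A_max, x$sd_A_max),
    t_peak_ms = fmt(x$mean_t_peak, x$sd_t_peak),
    A_peak_norm = fmt(x$mean_A_peak, x$sd_A_peak),
    d1_infl_norm = fmt(x$mean_d1_inflection, x$sd_d1_inflection),
    n_fail = x$n_fail,
    check.names = FALSE
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tidy a Monte Carlo error table
#'
#' @param x An `lfp_error_table`.
#' @param ... Unused.
#' @return A long tibble: `snr`, `index` (error-index name), `mean`, `sd`.
#' @method tidy lfp_error_table
#' @export
tidy.lfp_error_table <- function(x, ...) {
  means <- tidyr::pivot_longer(
    as_tibble(x)[, c("snr", grep("^mean_", names(x), value = TRUE))],
    -"snr", names_to = "index", values_to = "mean",
    names_prefix = "mean_")
  sds <- tidyr::pivot_longer(
    as_tibble(x)[, c("snr", grep("^sd_", names(x), value = TRUE))],
    -"snr", names_to = "index", values_to = "sd", names_prefix = "sd_")
  dplyr::left_join(means, sds, by = c("snr", "index"))
}

#' Summarize a Monte Carlo run
#'
#' @param x An `lfp_error_table`.
#' @param ... Unused.
#' @return A one-row tibble: number of levels, sweeps per level, total
#'   failures.
#' @method glance lfp_error_table
#' @export
glance.lfp_error_table <- function(x, ...) {
  errs <- attr(x, "sweep_errors")
  tibble(
    n_levels = nrow(x),
    n_sweeps = if (is.null(errs)) NA_integer_ else max(errs$sweep),
    n_fail_total = sum(x$n_fail)
  )
}

#' Write a Monte Carlo error table as CSV
#'
#' Writes one row per SNR level with both human-readable "mean (sd)" cells
#' and machine-readable mean/sd columns.
#'
#' @param x An `lfp_error_table`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_error_table <- function(x, path) {
  fmt <- function(m, s) ifelse(is.na(m), "", sprintf("%.4g (%.4g)", m, s))
  pretty <- data.frame(
    snr = ifelse(is.infinite(x$snr), "Inf", format(x$snr)),
    t_max_ms = fmt(x$mean_t_max, x$sd_t_max),
    A_max_norm = fmt(x$mean_A_max, x$sd_A_max),
    t_peak_ms = fmt(x$mean_t_peak, x$sd_t_peak),
    A_peak_norm = fmt(x$mean_A_peak, x$sd_A_peak),
    d1_inflection_norm = fmt(x$mean_d1_inflection, x$sd_d1_inflection),
    stringsAsFactors = FALSE
  )
  machine <- as.data.frame(x)[, setdiff(names(x), "snr")]
  utils::write.csv(cbind(pretty, machine), path, row.names = FALSE)
  invisible(path)
}
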