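#' Read a multi-sweep recording from delimited text
#'
#' The expected layout is columnar: the first column is the time vector in
#' ms, every remaining column is one sweep in mV. The delimiter (comma,
#' tab, or whitespace) is auto-detected; a single leading comment/header
#' line prefixed `#` is allowed and skipped. The time grid must be strictly
#' increasing and uniform to within `1e-6` relative.
#'
#' @param path Path to the text file.
#' @param sampling_frequency Optional sampling frequency in Hz; when given,
#'   the inferred sampling interval is cross-checked and a warning is
#'   issued on a mismatch exceeding 0.1%.
#' @return A long tibble with columns `time` (ms), `sweep` (integer index)
#'   and `amplitude` (mV); the inferred `dt` (ms) is attached as attribute
#'   `"dt"`.
#' @export
read_sweeps <- function(path, sampling_frequency = NULL) {
  mat <- parse_delim(path)
  if (ncol(mat) < 2) {
    abort("Input must have a time column plus at least one sweep column.",
          class = "lfp_error_format")
  }
  time <- mat[, 1]
  dts <- diff(time)
  bad <- which(dts <= 0)
  if (length(bad) > 0) {
    abort(sprintf("Time column is not strictly increasing at data line %d.",
                  bad[1] + 1L),
          class = "lfp_error_format")
  }
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 1e-6 * dt) {
    abort("Time grid is not uniform (relative deviation above 1e-6).",
          class = "lfp_error_format")
  }
  if (!is.null(sampling_frequency)) {
    dt_expected <- 1000 / sampling_frequency
    if (abs(dt - dt_expected) > 1e-3 * dt_expected) {
      warn(sprintf(
        "Inferred dt = %g ms differs from 1000/sampling_frequency = %g ms by more than 0.1%%.",
        dt, dt_expected), class = "lfp_warning_fs_mismatch")
    }
  }
  n_sweeps <- ncol(mat) - 1L
  time_rep <- rep(time, n_sweeps)
  sweep_idx <- rep(seq_len(n_sweeps), each = length(time))
  out <- tibble(
    time = time_rep,
    sweep = sweep_idx,
    amplitude = as.vector(mat[, -1, drop = FALSE])
  )
  attr(out, "dt") <- dt
  out
}

# Parse delimited numeric text into a matrix; errors carry line numbers.
parse_delim <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "lfp_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(sprintf("File is empty: %s", path), class = "lfp_error_format")
  }
  header <- NULL
  if (startsWith(lines[1], "#")) {
    header <- sub("^#\\s?", "", lines[1])
    lines <- lines[-1]
    if (length(lines) == 0) {
      abort("File contains only a header line.", class = "lfp_error_format")
    }
  }
  delim <- if (grepl(",", lines[1])) {
    ","
  } else if (grepl("\t", lines[1])) {
    "\t"
  } else {
    "ws"
  }
  split1 <- function(x) {
    if (delim == "ws") strsplit(trimws(x), "[ \t]+")[[1]]
    else strsplit(x, delim, fixed = TRUE)[[1]]
  }
  fields <- lapply(lines, split1)
  ncols <- lengths(fields)
  if (any(ncols != ncols[1])) {
    bad <- which(ncols != ncols[1])[1]
    abort(sprintf("Ragged row: data line %d has %d fields, expected %d.",
                  bad, ncols[bad], ncols[1]),
          class = "lfp_error_format")
  }
  num <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), nrow = length(lines),
           ncol = ncols[1], byrow = TRUE))
  if (anyNA(num)) {
    bad <- which(apply(is.na(num), 1, any))[1]
    abort(sprintf("Non-numeric value at data line %d.", bad),
          class = "lfp_error_format")
  }
  attr(num, "header") <- header
  num
}

#' Normalize a delimited recording to the canonical CSV layout
#'
#' Re-writes a tab-, space- or comma-delimited columnar recording as
#' comma-delimited text with full numeric precision; a leading `#` header
#' line, if present, is preserved as a metadata comment. Reading the
#' converted file yields numerically identical sweeps.
#'
#' @param path_in Input text file (first column time in ms, one column per
#'   sweep).
#' @param path_out Output CSV path.
#' @return `path_out`, invisibly.
#' @export
convert_matrix_input <- function(path_in, path_out) {
  mat <- parse_delim(path_in)
  header <- attr(mat, "header")
  con <- file(path_out, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(apply(mat, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = ",")
  }), con)
  invisible(path_out)
}

#' Session configuration for batch feature extraction
#'
#' Bundles the input location, recording metadata and detection parameters
#' for one batch run over all sweeps of a recording session.
#'
#' @param input_path Path to the delimited recording (see [read_sweeps()]).
#' @param experiment_name Nonempty name used to label output files.
#' @param depth_label Recording depth label (e.g. um), used in output file
#'   names (default `"0"`).
#' @param sampling_frequency Sampling frequency in Hz (cross-checked
#'   against the time column).
#' @param sigma Known noise standard deviation (mV); wins over
#'   `baseline_window` when both are given.
#' @param baseline_window Interval (ms) used to estimate `sigma` once from
#'   the pooled pre-stimulus baselines of all sweeps; defaults to
#'   `[0, window_start)` when `sigma` is absent.
#' @param output_dir Directory for output CSVs, or `NULL` to skip writing.
#' @param window_start,window_end,downsample_factor,onset_position,min_distance,rel_tol,gamma_fallback
#'   Passed to [detection_config()].
#' @return A list of class `session_config`.
#' @export
session_config <- function(input_path, experiment_name,
                           depth_label = "0", sampling_frequency = 50000,
                           window_start = 5, window_end = 50,
                           downsample_factor = 30, onset_position = 0,
                           min_distance = 5, sigma = NULL,
                           baseline_window = NULL, output_dir = NULL,
                           rel_tol = 1e-3, gamma_fallback = NULL) {
  if (!is.character(experiment_name) || !nzchar(experiment_name)) {
    abort("`experiment_name` must be a nonempty string.",
          class = "lfp_error_config")
  }
  if (sampling_frequency <= 0) {
    abort("`sampling_frequency` must be positive.", class = "lfp_error_config")
  }
  detection <- detection_config(window_start, window_end, downsample_factor,
                                onset_position, min_distance, rel_tol,
                                gamma_fallback)
  structure(
    list(input_path = input_path, experiment_name = experiment_name,
         depth_label = as.character(depth_label),
         sampling_frequency = sampling_frequency, detection = detection,
         sigma = sigma, baseline_window = baseline_window,
         output_dir = output_dir),
    class = "session_config"
  )
}

#' Run a batch feature-extraction session
#'
#' Reads every sweep of the recording, resolves the noise standard
#' deviation (an explicit `sigma` wins over `baseline_window`, with a
#' warning when both are given; with neither, the pooled pre-window
#' baseline `[0, window_start)` is used), extracts features from each
#' sweep, and writes a per-sweep feature table and a per-feature summary
#' as CSV named `<experiment>_<depth>.csv` and
#' `<experiment>_<depth>_summary.csv`. Failed sweeps keep their row with a
#' non-`"ok"` status; the run is deterministic given its inputs.
#'
#' @param config A [session_config()].
#' @return A list of class `lfp_session`: `features` (the
#'   [extract_features()] tibble), `summary` (tibble `feature`, `mean`,
#'   `sd`, `n` over successful sweeps), `sigma`, and `files` (paths
#'   written, if any).
#' @export
run_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  sweeps <- read_sweeps(config$input_path, config$sampling_frequency)

  sigma <- config$sigma
  if (!is.null(sigma) && !is.null(config$baseline_window)) {
    warn("Both `sigma` and `baseline_window` given; using `sigma`.",
         class = "lfp_warning_sigma_policy")
  }
  if (is.null(sigma)) {
    bw <- config$baseline_window %||% c(0, config$detection$window_start)
    # pooled baseline: center each sweep's segment, then one sd for all
    seg <- sweeps |>
      dplyr::filter(.data$time >= bw[1], .data$time < bw[2]) |>
      dplyr::group_by(.data$sweep) |>
      dplyr::mutate(amplitude = .data$amplitude - mean(.data$amplitude)) |>
      dplyr::ungroup()
    if (nrow(seg) < 8) {
      abort(sprintf("Baseline window [%g, %g) ms has %d samples; need >= 8.",
                    bw[1], bw[2], nrow(seg)), class = "lfp_error_window")
    }
    sigma <- sd(seg$amplitude)
    floor_val <- 1e-9 * max(abs(sweeps$amplitude))
    if (!is.finite(sigma) || sigma < floor_val) {
      warn("Pooled baseline is (nearly) noiseless; flooring sigma.",
           class = "lfp_warning_degenerate_noise")
      sigma <- floor_val
    }
  }

  features <- extract_features(sweeps, config$detection, sigma = sigma)
  summary <- summarize_features(features)

  files <- character(0)
  if (!is.null(config$output_dir)) {
    if (!dir.exists(config$output_dir)) {
      dir.create(config$output_dir, recursive = TRUE)
    }
    stem <- file.path(config$output_dir,
                      paste0(config$experiment_name, "_",
                             config$depth_label))
    feat_path <- paste0(stem, ".csv")
    sum_path <- paste0(stem, "_summary.csv")
    write_feature_table(features, feat_path, config, sigma)
    write_csv_plain(summary, sum_path)
    files <- c(features = feat_path, summary = sum_path)
  }

  structure(
    list(features = features, summary = summary, sigma = sigma,
         files = files, config = config),
    class = "lfp_session"
  )
}

#' @export
print.lfp_session <- function(x, ...) {
  n_ok <- sum(x$features$status != "failed")
  cat(sprintf(
    "<lfp_session> %s (depth %s): %d/%d sweeps detected, sigma = %.4g mV\n",
    x$config$experiment_name, x$config$depth_label, n_ok,
    nrow(x$features), x$sigma))
  print(x$summary)
  invisible(x)
}

summarize_features <- function(features) {
  ok <- features[features$status != "failed", , drop = FALSE]
  cols <- c("t_max", "A_max", "t_onset", "A_onset", "t_peak", "A_peak",
            "d1_inflection", "latency_param")
  if (nrow(ok) == 0) {
    warn("No sweep passed detection; summary is empty.",
         class = "lfp_warning_no_detections")
    return(tibble(feature = cols, mean = NA_real_, sd = NA_real_, n = 0L))
  }
  purrr::map_dfr(cols, function(cl) {
    v <- ok[[cl]][!is.na(ok[[cl]])]
    tibble(feature = cl, mean = mean(v), sd = sd(v), n = length(v))
  })
}

# Full-precision CSV writers (no timestamps: outputs are byte-reproducible).
fmt_cell <- function(x) {
  if (is.numeric(x)) ifelse(is.na(x), "", sprintf("%.17g", x))
  else ifelse(is.na(x), "", as.character(x))
}

write_csv_plain <- function(df, path, comments = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines(paste(names(df), collapse = ","), con)
  cells <- vapply(df, fmt_cell, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  writeLines(apply(cells, 1, paste, collapse = ","), con)
  invisible(path)
}

write_feature_table <- function(features, path, config, sigma) {
  det <- config$detection
  comments <- c(
    sprintf("experiment: %s", config$experiment_name),
    sprintf("depth: %s", config$depth_label),
    sprintf("sampling_frequency_hz: %g", config$sampling_frequency),
    sprintf("window_ms: [%g, %g)", det$window_start, det$window_end),
    sprintf("downsample_factor: %d", det$downsample_factor),
    sprintf("onset_position: %g", det$onset_position),
    sprintf("min_distance_ms: %g", det$min_distance),
    sprintf("sigma_mv: %.17g", sigma)
  )
  cols <- c("sweep", "t_max", "A_max", "t_onset", "A_onset", "t_peak",
            "A_peak", "d1_inflection", "latency_param", "status",
            "t_inflection", "A_peak_signed", "gamma_d1", "gamma_d2",
            "detail")
  write_csv_plain(features[, cols], path, comments)
}

#' Read back a written feature table
#'
#' Companion to [run_session()]: parses the CSV it writes (metadata
#' comment lines plus one row per sweep) back into a tibble.
#'
#' @param path Path to a feature-table CSV.
#' @return A tibble with the same columns as the written table.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  as_tibble(df)
}
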