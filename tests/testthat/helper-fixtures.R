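# Shared fixtures, all generated in code.

# A smooth single-sweep tibble on a uniform grid.
smooth_sweep <- function(n = 64, dt = 0.5, t0 = 0,
                         f = function(t) exp(-(t - 12)^2 / 18)) {
  t <- t0 + dt * (seq_len(n) - 1)
  tibble::tibble(time = t, amplitude = f(t))
}

# Random (xi, d) pair with a reachable discrepancy target.
random_xi_d <- function(n = 40, seed = 1) {
  withr::with_seed(seed, list(
    xi = stats::rnorm(n, sd = 2),
    d = sort(abs(stats::rnorm(n, sd = 3)), decreasing = TRUE)
  ))
}

# Direct solution of the penalized least-squares normal equations,
# independent of the SVD path used by the package.
direct_tikhonov <- function(y, G, F, gamma) {
  drop(solve(crossprod(G) + gamma * crossprod(F), crossprod(G, y)))
}

# Write a delimited multi-sweep file; returns the path.
write_sweep_file <- function(time, sweeps, path = tempfile(fileext = ".txt"),
                             delim = "\t", header = NULL) {
  mat <- cbind(time, sweeps)
  lines <- apply(mat, 1, function(r) paste(sprintf("%.10g", r),
                                           collapse = delim))
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  writeLines(lines, path)
  path
}

# Small-session template: 5 kHz, 80 ms, so session tests stay light.
session_spec <- function() {
  template_spec(
    components = list(
      lfp_component("gauss", amplitude = 0.3, center = 8, width = 2.2),
      lfp_component("gamma", amplitude = -1.1, onset = 8, shape = 3.25,
                    scale = 16 / 3)
    ),
    fs = 5000, duration = 80
  )
}
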