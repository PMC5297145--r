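#' Specify a parametric noiseless LFP template
#'
#' A template is a sum of smooth bump primitives chosen to emulate the
#' early morphology of a whisker-evoked LFP: a small positive first
#' maximum around 8 ms, an inflection around 10 ms, and the main negative
#' peak around 20 ms post-stimulus. Two primitives are available:
#' a Gaussian bump, and a peak-normalized gamma-shaped bump (skewed, with a
#' smooth onset) that reproduces the fast-drop/slow-recovery shape of the
#' negative deflection. The composed waveform is twice continuously
#' differentiable, so all ground-truth features have analytic derivatives.
#'
#' @param components List of components from [lfp_component()]. The default
#'   places a positive Gaussian first maximum (0.3 mV, center 8 ms, width
#'   2.2 ms), a negative gamma bump (-1.1 mV, onset 8 ms, shape 3.25,
#'   scale 16/3, so the trough falls at 20 ms), and the two slow late
#'   components of the canonical evoked-LFP profile: a slow positive
#'   deflection (0.12 mV around 120 ms) and a slow negative valley
#'   (-0.18 mV around 300 ms). The late components lie outside the usual
#'   analysis window but contribute to the signal variance that fixes the
#'   noise level at a given SNR.
#' @param fs Sampling frequency in Hz (default 50000).
#' @param duration Template duration in ms (default 500, the length of a
#'   stimulus-locked recording epoch).
#' @return A list of class `template_spec`.
#' @export
template_spec <- function(components = NULL, fs = 50000, duration = 500) {
  if (is.null(components)) {
    components <- c(fast_components(0.3, 8, 1.1, 20), slow_components())
  }
  stopifnot(fs > 0, duration > 0, length(components) >= 1)
  structure(list(components = components, fs = fs, duration = duration),
            class = "template_spec")
}

# Fast early morphology: positive first maximum at t = c0 (the gamma bump
# onset coincides with the Gaussian center, so the analytic maximum falls
# exactly at c0) and skewed negative deflection with trough at t_peak.
fast_components <- function(a_max, c0, a_peak, t_peak) {
  list(
    lfp_component("gauss", amplitude = a_max, center = c0, width = 2.2),
    lfp_component("gamma", amplitude = -a_peak, onset = c0, shape = 3.25,
                  scale = (t_peak - c0) / 2.25)
  )
}

# Slow late components: positive deflection (~60-200 ms) and negative
# valley (~200-500 ms) with gradual return to baseline.
slow_components <- function() {
  list(
    lfp_component("gauss", amplitude = 0.12, center = 120, width = 40),
    lfp_component("gauss", amplitude = -0.18, center = 300, width = 90)
  )
}

#' Define one template bump primitive
#'
#' @param type `"gauss"` for `a exp(-(t - center)^2 / (2 width^2))`, or
#'   `"gamma"` for the peak-normalized gamma bump
#'   `a (x / xm)^(shape - 1) exp(-(x - xm) / scale)` with `x = t - onset`,
#'   `xm = (shape - 1) scale` (zero for `t <= onset`).
#' @param amplitude Peak value in mV (sign gives the polarity).
#' @param center,width Gaussian parameters (ms).
#' @param onset,scale Gamma bump onset and scale (ms).
#' @param shape Gamma shape parameter (dimensionless, > 3 so the waveform
#'   stays twice differentiable at the onset); the trough/peak falls at
#'   `onset + (shape - 1) scale`.
#' @return A list describing the component.
#' @export
lfp_component <- function(type = c("gauss", "gamma"), amplitude,
                          center = NULL, width = NULL,
                          onset = NULL, shape = NULL, scale = NULL) {
  type <- match.arg(type)
  if (type == "gauss") {
    stopifnot(is.numeric(center), is.numeric(width), width > 0)
    list(shape = "gauss", amplitude = amplitude, center = center,
         width = width)
  } else {
    stopifnot(is.numeric(onset), is.numeric(shape), is.numeric(scale),
              scale > 0)
    if (shape <= 3) {
      abort("Gamma components need shape > 3 for a twice-differentiable onset.",
            class = "lfp_error_morphology")
    }
    list(shape = "gamma", amplitude = amplitude, onset = onset,
         shape_k = shape, scale = scale)
  }
}

comp_eval <- function(comp, t, deriv = 0) {
  if (comp$shape == "gauss") {
    z <- (t - comp$center) / comp$width
    e <- comp$amplitude * exp(-z^2 / 2)
    switch(as.character(deriv),
      "0" = e,
      "1" = -e * z / comp$width,
      "2" = e * (z^2 - 1) / comp$width^2
    )
  } else {
    k <- comp$shape_k
    th <- comp$scale
    xm <- (k - 1) * th
    x <- t - comp$onset
    out <- numeric(length(t))
    pos <- x > 0
    xp <- x[pos]
    h <- (xp / xm)^(k - 1) * exp(-(xp - xm) / th)
    s <- (k - 1) / xp - 1 / th
    val <- switch(as.character(deriv),
      "0" = h,
      "1" = h * s,
      "2" = h * (s^2 - (k - 1) / xp^2)
    )
    out[pos] <- comp$amplitude * val
    out
  }
}

template_value <- function(spec, t, deriv = 0) {
  Reduce(`+`, lapply(spec$components, comp_eval, t = t, deriv = deriv))
}

#' Sample a noiseless template and compute its ground-truth features
#'
#' Samples the composed waveform on the `fs` grid and derives the analytic
#' ground truth by dense evaluation (0.005 ms grid) of the closed-form
#' first and second derivatives: first maximum (earliest positive-to-
#' negative zero of the first derivative), global negative peak, and the
#' inflection point between them (sign-changing zero of the second
#' derivative; if several, the one with steepest descent).
#'
#' @param spec A [template_spec()].
#' @return A list of class `lfp_template` with `sweep` (tibble `time`,
#'   `amplitude`), `ground_truth` (one-row tibble: `t_max`, `A_max`,
#'   `t_peak`, `A_peak`, `A_peak_signed`, `t_inflection`,
#'   `d1_inflection`), `sd_lfp` (sample sd of the template over its full
#'   duration, used by [add_noise()]), and `spec`.
#' @section Errors: a spec whose composed waveform has no negative
#'   deflection, or no maximum preceding the trough, raises
#'   `lfp_error_morphology`.
#' @export
make_template <- function(spec = template_spec()) {
  stopifnot(inherits(spec, "template_spec"))
  dt <- 1000 / spec$fs
  t <- seq(0, spec$duration - dt, by = dt)
  v <- template_value(spec, t)

  td <- seq(0, spec$duration, by = 0.005)
  vd <- template_value(spec, td)
  d1 <- template_value(spec, td, 1)
  d2 <- template_value(spec, td, 2)

  if (min(vd) >= 0) {
    abort("Template has no negative deflection.", class = "lfp_error_morphology")
  }
  i_peak <- which.min(vd)
  nb <- length(td) - 1
  down <- which(d1[1:nb] > 0 & d1[2:(nb + 1)] <= 0)
  down <- down[down < i_peak & vd[down] > 0]
  if (length(down) == 0) {
    abort("Template has no positive first maximum preceding the negative peak.",
          class = "lfp_error_morphology")
  }
  i_max <- down[1]
  # refine on the dense grid: crossing bracket -> local extremum
  t_max <- td[i_max + which.max(vd[i_max + 0:1]) - 1]
  A_max <- max(vd[i_max + 0:1])
  t_peak <- td[i_peak]
  A_peak_signed <- vd[i_peak]

  mid <- i_max:(i_peak - 1)
  cross <- mid[d2[mid] * d2[mid + 1] < 0]
  cross <- cross[td[cross] > t_max & td[cross + 1] < t_peak]
  if (length(cross) > 0) {
    i_inf <- cross[which.max(abs(d1[cross]))]
    t_inf <- (td[i_inf] + td[i_inf + 1]) / 2
    d1_inf <- template_value(spec, t_inf, 1)
  } else {
    t_inf <- NA_real_
    d1_inf <- NA_real_
  }

  structure(
    list(
      sweep = tibble(time = t, amplitude = v),
      ground_truth = tibble(
        t_max = t_max, A_max = A_max, t_peak = t_peak,
        A_peak = abs(A_peak_signed), A_peak_signed = A_peak_signed,
        t_inflection = t_inf, d1_inflection = d1_inf
      ),
      sd_lfp = sd(v),
      spec = spec
    ),
    class = "lfp_template"
  )
}

#' @export
print.lfp_template <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf(
    "<lfp_template> %d samples at %g kHz over %g ms\n  truth: t_max %.2f ms (%.3f mV), inflection %.2f ms (d1 %.3f mV/ms), t_peak %.2f ms (%.3f mV)\n",
    nrow(x$sweep), x$spec$fs / 1000, x$spec$duration,
    gt$t_max, gt$A_max, gt$t_inflection, gt$d1_inflection, gt$t_peak,
    gt$A_peak
  ))
  invisible(x)
}

#' Add white noise at a controlled signal-to-noise ratio
#'
#' SNR is defined as the variance ratio `sd_LFP^2 / sd_noise^2`, so the
#' added noise has standard deviation `sd_LFP / sqrt(snr)`, where `sd_LFP`
#' is the sample standard deviation of the noiseless template over its full
#' duration. `snr = Inf` returns the template unchanged. Randomness comes
#' from the caller's RNG stream; seed it for reproducibility.
#'
#' @param template An `lfp_template` from [make_template()], or a data
#'   frame with `time` and `amplitude` (then supply `sd_lfp` or it is
#'   computed from the data).
#' @param snr Target signal-to-noise ratio (> 0, may be `Inf`).
#' @param sd_lfp Optionally override the signal standard deviation (mV).
#' @return A tibble with `time` and `amplitude` (noisy sweep), with the
#'   noise standard deviation attached as attribute `"sd_noise"`.
#' @export
add_noise <- function(template, snr, sd_lfp = NULL) {
  if (!is.numeric(snr) || length(snr) != 1 || snr <= 0) {
    abort("`snr` must be a single positive number (possibly Inf).",
          class = "lfp_error_domain")
  }
  if (inherits(template, "lfp_template")) {
    df <- template$sweep
    sd_lfp <- sd_lfp %||% template$sd_lfp
  } else {
    df <- as_tibble(template[, c("time", "amplitude")])
    sd_lfp <- sd_lfp %||% sd(df$amplitude)
  }
  if (is.infinite(snr)) {
    attr(df, "sd_noise") <- 0
    return(df)
  }
  sd_noise <- sd_lfp / sqrt(snr)
  out <- dplyr::mutate(df, amplitude = .data$amplitude +
                         rnorm(dplyr::n(), mean = 0, sd = sd_noise))
  attr(out, "sd_noise") <- sd_noise
  out
}

#' Template presets for a depth series
#'
#' Seven synthetic presets spanning recording depths 320-920 um in rat S1
#' barrel cortex, varying first-maximum latency and amplitude, negative-
#' peak latency (17-20 ms) and amplitude (0.6-1.1 mV) in the range reported
#' for real depth series. These are synthetic stand-ins constructed from
#' the parametric family, not waveforms derived from recordings.
#'
#' @return A named list of [template_spec()] objects, named by depth in um.
#' @export
template_presets <- function() {
  mk <- function(c0, a_max, t_peak, a_peak) {
    template_spec(components = c(fast_components(a_max, c0, a_peak, t_peak),
                                 slow_components()))
  }
  list(
    "320" = mk(10.9, 0.09, 19.8, 0.61),
    "420" = mk(9.4, 0.15, 18.3, 1.07),
    "520" = mk(8.8, 0.12, 18.8, 1.00),
    "620" = mk(8.4, 0.20, 18.0, 1.05),
    "720" = mk(8.0, 0.30, 17.3, 1.12),
    "820" = mk(8.1, 0.25, 17.8, 0.95),
    "920" = mk(8.2, 0.18, 18.2, 0.76)
  )
}
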