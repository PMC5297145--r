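test_that("preprocess windows and decimates with the documented conventions", {
  t <- seq(0, 500 - 0.02, by = 0.02)  # 50 kHz
  sw <- tibble::tibble(time = t, amplitude = sin(t / 10))
  cfg <- detection_config(window_start = 5, window_end = 50,
                          downsample_factor = 30)
  pre <- preprocess(sw, cfg)
  expect_equal(diff(pre$time)[1], 0.6, tolerance = 1e-9)
  expect_equal(nrow(pre), 75)
  expect_gte(min(pre$time), 5)
  expect_lt(max(pre$time), 50)

  # factor 1 is the identity on the windowed segment
  cfg1 <- detection_config(downsample_factor = 1)
  pre1 <- preprocess(sw, cfg1)
  expect_equal(pre1$amplitude,
               sw$amplitude[sw$time >= 5 & sw$time < 50])
})

test_that("preprocess handles multiple sweeps and empty windows", {
  t <- seq(0, 100, by = 0.5)
  long <- dplyr::bind_rows(
    tibble::tibble(time = t, sweep = 1L, amplitude = sin(t)),
    tibble::tibble(time = t, sweep = 2L, amplitude = cos(t))
  )
  pre <- preprocess(long, detection_config(downsample_factor = 2))
  expect_equal(sort(unique(pre$sweep)), c(1L, 2L))
  expect_error(
    preprocess(tibble::tibble(time = 1:10, amplitude = 1:10),
               detection_config(window_start = 40, window_end = 45,
                                min_distance = 1)),
    class = "lfp_error_window")
})

test_that("zero-crossing extrema detection finds analytic extrema", {
  # analytic curve with max at 8 and min at 20
  t <- seq(5, 49.4, by = 0.6)
  f <- function(t) 0.4 * exp(-(t - 8)^2 / 8) - exp(-(t - 20)^2 / 30)
  d1 <- function(t) -0.4 * (t - 8) / 4 * exp(-(t - 8)^2 / 8) +
    2 * (t - 20) / 30 * exp(-(t - 20)^2 / 30)
  grid <- tibble::tibble(time = t, smoothed = f(t), d1 = d1(t))
  ext <- find_extrema(grid, detection_config(min_distance = 5))
  expect_lt(abs(ext$t_max - 8), 0.6 + 1e-9)
  expect_lt(abs(ext$t_peak - 20), 0.6 + 1e-9)
  expect_equal(ext$A_peak, abs(ext$A_peak_signed))
  expect_gt(ext$A_peak, 0.9)
})

test_that("detection fails cleanly without a sign change", {
  t <- seq(0, 30, by = 0.5)
  grid <- tibble::tibble(time = t, smoothed = -t, d1 = rep(-1, length(t)))
  expect_error(find_extrema(grid, detection_config()),
               class = "lfp_error_detection")
})

test_that("the deeper of two local minima is selected as the negative peak", {
  t <- seq(0, 45, by = 0.5)
  f <- function(t) 0.5 * exp(-(t - 5)^2 / 4) - 0.4 * exp(-(t - 15)^2 / 6) +
    0.3 * exp(-(t - 24)^2 / 6) - exp(-(t - 33)^2 / 8)
  h <- 1e-5
  grid <- tibble::tibble(time = t, smoothed = f(t),
                         d1 = (f(t + h) - f(t - h)) / (2 * h))
  ext <- find_extrema(grid, detection_config(min_distance = 5))
  expect_lt(abs(ext$t_peak - 33), 0.5 + 1e-9)
  # and the min-distance constraint can exclude every maximum
  expect_error(find_extrema(grid, detection_config(min_distance = 40)),
               class = "lfp_error_detection")
})

test_that("onset interpolates between first maximum and peak and snaps to the grid", {
  t <- seq(5, 49.4, by = 0.6)
  grid <- tibble::tibble(time = t, smoothed = sin(t / 5))
  p0 <- locate_onset(grid, t_max = 8, t_peak = 20, p = 0)
  expect_equal(p0$t_onset, t[which.min(abs(t - 8))])
  p1 <- locate_onset(grid, t_max = 8, t_peak = 20, p = 1)
  expect_equal(p1$t_onset, t[which.min(abs(t - 20))])
  ph <- locate_onset(grid, t_max = 8, t_peak = 20, p = 0.5)
  expect_equal(ph$t_onset, t[which.min(abs(t - 14))])
  expect_equal(ph$A_onset, grid$smoothed[ph$i_onset])
})

test_that("inflection detection verifies the sign change and breaks ties by steepest descent", {
  t <- seq(0, 30, by = 0.5)
  # d2 crosses zero at 10.2 (descending d1 extremum) only
  d1 <- -exp(-(t - 10.2)^2 / 8)
  d2 <- (t - 10.2) / 4 * exp(-(t - 10.2)^2 / 8)
  grid <- tibble::tibble(time = t, d1 = d1, d2 = d2)
  res <- locate_inflection(grid, t_max = 4, t_peak = 25)
  expect_lt(abs(res$t_inflection - 10.2), 0.5 + 1e-9)
  expect_equal(res$d1_inflection, d1[res$i_inflection])

  # strictly positive d2: nothing to find
  grid2 <- tibble::tibble(time = t, d1 = d1, d2 = rep(1, length(t)))
  expect_error(locate_inflection(grid2, 4, 25),
               class = "lfp_error_inflection")

  # two sign-changing zeros; the one where |d1| is larger wins
  d1b <- -0.3 - 0.7 * exp(-(t - 18.2)^2 / 6)
  d2b <- sin(pi * (t - 6.2) / 12)  # zeros at 6.2, 18.2, 30.2
  grid3 <- tibble::tibble(time = t, d1 = d1b, d2 = d2b)
  res3 <- locate_inflection(grid3, t_max = 2, t_peak = 28)
  expect_lt(abs(res3$t_inflection - 18.2), 0.5 + 1e-9)
})

test_that("full pipeline recovers template ground truth without noise", {
  tpl <- make_template()
  gt <- tpl$ground_truth
  cfg <- detection_config()
  sigma <- 1e-9 * max(abs(tpl$sweep$amplitude))
  feats <- extract_features(tpl$sweep, cfg, sigma = sigma)
  expect_equal(feats$status, "ok")
  expect_lte(abs(feats$t_max - gt$t_max), 0.6)
  expect_lte(abs(feats$t_peak - gt$t_peak), 0.6)
  expect_lte(abs(feats$t_inflection - gt$t_inflection), 0.6)
  expect_lt(abs(feats$A_max - gt$A_max) / gt$A_max, 0.02)
  expect_lt(abs(feats$A_peak - gt$A_peak) / gt$A_peak, 0.02)
  expect_equal(feats$t_onset, feats$t_max)  # p = 0
  expect_equal(feats$latency_param, feats$t_peak - feats$t_onset)
})

test_that("a flat sweep is reported as failed, not dropped", {
  t <- seq(0, 100, by = 0.2)
  flat <- tibble::tibble(time = t, amplitude = rep(0, length(t)))
  feats <- extract_features(flat, detection_config(downsample_factor = 4),
                            sigma = 0.01)
  expect_equal(nrow(feats), 1)
  expect_equal(feats$status, "failed")
  expect_true(is.na(feats$t_peak))
  expect_true(nzchar(feats$detail))
})

test_that("feature latencies are equivariant to time shifts", {
  tpl <- make_template()
  sigma <- tpl$sd_lfp / sqrt(10)
  for (seed in 1:5) {
    noisy <- withr::with_seed(seed, add_noise(tpl, snr = 10))
    base <- extract_features(noisy, detection_config(), sigma = sigma)
    k <- seed * 50  # shift by k raw samples
    shift <- k * 0.02
    shifted <- dplyr::mutate(noisy, time = .data$time + shift)
    cfg_s <- detection_config(window_start = 5 + shift,
                              window_end = 50 + shift)
    moved <- extract_features(shifted, cfg_s, sigma = sigma)
    expect_equal(moved$t_max, base$t_max + shift, tolerance = 1e-9)
    expect_equal(moved$t_peak, base$t_peak + shift, tolerance = 1e-9)
    expect_equal(moved$t_inflection, base$t_inflection + shift,
                 tolerance = 1e-9)
    expect_equal(moved$A_peak, base$A_peak, tolerance = 1e-12)
  }
})

test_that("amplitudes scale with the sweep while latencies are unchanged", {
  tpl <- make_template()
  sigma <- tpl$sd_lfp / sqrt(10)
  for (seed in 1:5) {
    noisy <- withr::with_seed(seed + 10, add_noise(tpl, snr = 10))
    base <- extract_features(noisy, detection_config(), sigma = sigma)
    c_scale <- c(0.5, 2, 5, 0.1, 10)[seed]
    scaled <- dplyr::mutate(noisy, amplitude = .data$amplitude * c_scale)
    res <- extract_features(scaled, detection_config(),
                            sigma = sigma * c_scale)
    expect_equal(res$t_max, base$t_max)
    expect_equal(res$t_peak, base$t_peak)
    expect_equal(res$A_max, base$A_max * c_scale, tolerance = 1e-9)
    expect_equal(res$A_peak, base$A_peak * c_scale, tolerance = 1e-9)
    expect_equal(res$d1_inflection, base$d1_inflection * c_scale,
                 tolerance = 1e-9)
  }
})

test_that("ordering and min-distance invariants hold on noisy sweeps", {
  tpl <- make_template()
  cfg <- detection_config(onset_position = 0.3)
  sigma3 <- tpl$sd_lfp / sqrt(3)
  for (seed in 1:10) {
    noisy <- withr::with_seed(seed + 40, add_noise(tpl, snr = 3))
    f <- extract_features(noisy, cfg, sigma = sigma3)
    if (f$status == "failed") next
    expect_lte(f$t_max, f$t_onset)
    expect_lte(f$t_onset, f$t_peak)
    expect_gte(f$t_peak - f$t_max, cfg$min_distance)
    if (!is.na(f$t_inflection)) {
      expect_gt(f$t_inflection, f$t_max)
      expect_lt(f$t_inflection, f$t_peak)
    }
  }
})
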