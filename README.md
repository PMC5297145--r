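# lfpextract

Automatic detection of latency and amplitude features in stimulus-evoked
local field potentials (LFPs), for electrophysiologists who record
hundreds of stimulus-locked sweeps per session (e.g. whisker-evoked
responses in rat barrel cortex) and need objective, reproducible feature
tables instead of manual cursor placement.

## The method

An evoked LFP has a stereotyped early morphology: a small **first
maximum** (used as the response onset), an **inflection point**, and the
main **negative peak** associated with cortical layer activation. All
three are defined by zeros of time-derivatives, and differentiating a
noisy sweep amplifies noise because the problem is ill-conditioned.
`lfpextract` therefore estimates the derivatives by Phillips–Tikhonov
regularization. With the sweep samples `y` modelled as

    y = G u + v,

where `u` holds the samples of the first (or second) time-derivative,
`G` is the lower-triangular Toeplitz integration operator (first column
all ones for order 1, `1, 2, …, N` for order 2, scaled by `dt` and `dt²`
so `u` is in mV/ms and mV/ms²), and `v` is white noise with standard
deviation `σ`, the regularized estimate is

    û = (GᵀG + γ FᵀF)⁻¹ Gᵀ y,

with `F` the second-difference penalty operator (first column
`1, −2, 1, 0, …`). The parameter `γ` is chosen by the **discrepancy
criterion**: using the SVD `UᵀHV = D` of `H = GF⁻¹` (computed once per
sweep geometry and cached), the weighted residual sum of squares

    WRSS(γ) = Σᵢ (γ ξᵢ / (dᵢ² + γ))²,   ξ = Uᵀy,

is monotone in `γ`, and `γ` is tuned by bisection until
`WRSS(γ) = N σ²`. Each trial value costs only O(N). The estimate is then
`û = F⁻¹ V n` with `nᵢ = dᵢ ξᵢ / (dᵢ² + γ)`, and the regularized sweep
`Gû` plus normalized residuals `(y − Gû)/σ` come out as by-products.

Features are detected from zero-crossings: candidate maxima/minima where
the regularized first derivative changes sign, the negative peak as the
most negative candidate, the first maximum as the earliest candidate
preceding the peak by a user-set minimum distance, the onset at a
relative position `p ∈ [0, 1]` between them, and the inflection point as
the sign-changing zero of the second derivative inside the
maximum-to-peak interval.

The package also ships a parametric template generator with analytic
ground truth and a Monte Carlo driver that measures estimation error as
a function of SNR (`SNR = sd²_LFP / sd²_noise`).

## Worked example

```r
library(lfpextract)

tpl <- make_template()          # canonical synthetic evoked-LFP template
tpl
#> <lfp_template> 25000 samples at 50 kHz over 500 ms
#>   truth: t_max 8.00 ms (0.301 mV), inflection 10.91 ms (d1 -0.221 mV/ms), t_peak 19.98 ms (1.096 mV)

noisy <- withr::with_seed(1, add_noise(tpl, snr = 10))
feats <- extract_features(noisy, detection_config(),
                          sigma = tpl$sd_lfp / sqrt(10))
feats[, c("t_max", "A_max", "t_peak", "A_peak", "d1_inflection", "status")]
#>   t_max  A_max t_peak A_peak d1_inflection status
#> 1     8 0.2745   20.6  1.099       -0.2268     ok
```

The detected first maximum (8 ms, 0.27 mV), negative peak (20.6 ms,
1.10 mV) and inflection-point derivative (−0.23 mV/ms) recover the
template's ground truth to about one decimated sample (dt = 0.6 ms after
the default 30× decimation of a 50 kHz sweep) despite SNR 10 noise. The
fit itself can be inspected:

```r
est <- estimate_derivative(preprocess(noisy, detection_config()),
                           sigma = tpl$sd_lfp / sqrt(10))
glance(est)
#>   order     n    dt gamma  wrss discrepancy_target  sigma
#> 1     1    75 0.600  7.99 0.268              0.269 0.0598
```

`wrss` matches the discrepancy target `N σ²` at the selected `γ`, i.e.
the residual misfit equals its statistical expectation under the noise
model. `autoplot(est)` draws the raw sweep, the regularized sweep, the
derivative and the normalized residuals; `plot_features()` marks the
detected points; `autoplot()` on a `run_monte_carlo()` result shows
error boxplots by SNR.

Batch processing of a columnar recording (first column time in ms, one
column per sweep) is one call, or one shell command:

```r
sess <- run_session(session_config("recording.txt", "exp1", depth_label = "720",
                                   output_dir = "results"))
```

```sh
exec/lfpextract extract --input recording.txt --experiment exp1 --depth 720
```

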