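test_that("integration and penalty operators have the documented Toeplitz structure", {
  for (dt in c(1, 0.6)) {
    ops1 <- build_operators(8, order = 1, dt = dt, cache = FALSE)
    expect_equal(ops1$G[, 1], rep(1, 8) * dt)
    expect_equal(ops1$G[8, ], rev(rep(1, 8)) * dt)
    expect_true(all(ops1$G[upper.tri(ops1$G)] == 0))
    # Toeplitz: constant along diagonals
    for (k in 0:6) {
      expect_equal(unique(ops1$G[cbind((1 + k):8, 1:(8 - k))]), dt)
    }

    ops2 <- build_operators(8, order = 2, dt = dt, cache = FALSE)
    expect_equal(ops2$G[, 1], (1:8) * dt^2)
    expect_true(all(ops2$G[upper.tri(ops2$G)] == 0))

    expect_equal(ops1$F[, 1], c(1, -2, 1, rep(0, 5)))
    expect_equal(diag(ops1$F), rep(1, 8))
  }
})

test_that("the SVD factors diagonalize H = G F^-1", {
  for (cfg in list(c(16, 1, 1), c(24, 2, 0.6), c(40, 1, 0.02))) {
    ops <- build_operators(cfg[1], cfg[2], cfg[3], cache = FALSE)
    expect_lt(max(abs(crossprod(ops$U) - diag(ops$n))), 1e-10)
    expect_lt(max(abs(crossprod(ops$V) - diag(ops$n))), 1e-10)
    expect_true(all(ops$d >= 0))
    H <- ops$G %*% solve(ops$F)
    D <- t(ops$U) %*% H %*% ops$V
    expect_lt(max(abs(D - diag(ops$d))), 1e-10 * max(ops$d))
  }
})

test_that("operator construction rejects invalid sizes and orders", {
  expect_error(build_operators(4, 1), class = "lfp_error_sizing")
  expect_error(build_operators(16, 3), class = "lfp_error_order")
  expect_error(build_operators(16, 1, dt = 0), class = "lfp_error_domain")
})

test_that("operator cache returns the same decomposition object", {
  a <- build_operators(12, 1, 0.25)
  b <- build_operators(12, 1, 0.25)
  expect_identical(a, b)
})

test_that("WRSS matches hand-computed values and limits", {
  expect_equal(wrss_at(1, xi = c(1, 1), d = c(1, 1)), 0.5)
  expect_equal(wrss_at(0, xi = c(2, 3), d = c(1, 2)), 0)
  # gamma -> infinity limit is sum(xi^2)
  expect_equal(wrss_at(1e12, xi = c(2, 3), d = c(1, 2)), 13, tolerance = 1e-6)
  expect_error(wrss_at(-1, c(1), c(1)), class = "lfp_error_domain")
})

test_that("WRSS is nondecreasing in gamma on random inputs", {
  for (seed in 1:5) {
    p <- random_xi_d(30, seed)
    w <- vapply(10^seq(-8, 8, length.out = 60), wrss_at, numeric(1),
                xi = p$xi, d = p$d)
    expect_true(all(diff(w) >= -1e-12 * max(w)))
  }
})

test_that("discrepancy root is recovered where planted and matches a grid scan", {
  p <- random_xi_d(40, seed = 7)
  # plant the root at gamma = 1
  target <- wrss_at(1, p$xi, p$d)
  sigma <- sqrt(target / 40)
  sel <- select_gamma(p$xi, p$d, sigma, 40)
  expect_equal(sel$gamma, 1, tolerance = 0.01)
  expect_lt(abs(sel$wrss - target), 1e-3 * target)

  # closed form: xi = (1,1), d = (1,1), N sigma^2 = 0.5 -> gamma = 1
  sel2 <- select_gamma(c(1, 1), c(1, 1), sigma = 0.5, n_samples = 2)
  expect_equal(sel2$gamma, 1, tolerance = 0.01)

  # dense log-grid oracle on seeded inputs
  for (seed in 1:5) {
    q <- random_xi_d(32, seed + 100)
    sigma <- 0.3 * sqrt(sum(q$xi^2) / 32)
    sel <- select_gamma(q$xi, q$d, sigma, 32)
    grid <- 10^seq(-12, 12, length.out = 24001)
    wg <- vapply(grid, wrss_at, numeric(1), xi = q$xi, d = q$d)
    g_star <- grid[which.min(abs(wg - 32 * sigma^2))]
    expect_equal(sel$gamma, g_star, tolerance = 5e-3)
  }
})

test_that("an unreachable discrepancy target raises a no-root error with context", {
  p <- random_xi_d(20, seed = 3)
  sigma <- 10 * sqrt(sum(p$xi^2) / 20)
  err <- expect_error(select_gamma(p$xi, p$d, sigma, 20),
                      class = "lfp_error_noroot")
  expect_equal(err$target, 20 * sigma^2)
  expect_equal(err$supremum, sum(p$xi^2))
})

test_that("SVD-path estimate equals the direct penalized least-squares solution", {
  for (seed in 1:6) {
    n <- c(16, 24, 32, 48, 64, 20)[seed]
    order <- if (seed %% 2 == 0) 2 else 1
    sw <- withr::with_seed(seed, {
      t <- 0.5 * (seq_len(n) - 1)
      tibble::tibble(time = t,
                     amplitude = sin(t / 3) + stats::rnorm(n, sd = 0.1))
    })
    gamma <- 10^(seed - 3)
    est <- estimate_derivative(sw, order = order, sigma = 0.1, gamma = gamma)
    ops <- build_operators(n, order, 0.5)
    u_direct <- direct_tikhonov(sw$amplitude, ops$G, ops$F, gamma)
    expect_lt(max(abs(est$u_hat - u_direct)), 1e-8 * max(abs(u_direct)))
  }
})

test_that("reconstruction identity holds: smoothed + sigma * residuals = y", {
  sw <- withr::with_seed(11, {
    t <- 0.2 * (0:99)
    tibble::tibble(time = t,
                   amplitude = cos(t) + stats::rnorm(100, sd = 0.05))
  })
  for (order in 1:2) {
    est <- estimate_derivative(sw, order = order, sigma = 0.05)
    recon <- est$smoothed + est$sigma * est$residuals_norm
    expect_lt(max(abs(recon - sw$amplitude)), 1e-10 * max(abs(sw$amplitude)))
    expect_equal(est$wrss, wrss_at(est$gamma, est$xi,
                                   build_operators(100, order, 0.2)$d))
  }
})

test_that("regularized first derivative recovers the derivative of a cubic", {
  t <- seq(1, 3, by = 0.02)
  sw <- tibble::tibble(time = t, amplitude = t^3)
  est <- estimate_derivative(sw, order = 1, sigma = 1e-9 * 27)
  truth <- 3 * t^2
  interior <- seq(ceiling(length(t) / 6), floor(5 * length(t) / 6))
  rel <- abs(est$u_hat[interior] - truth[interior]) / truth[interior]
  expect_lt(max(rel), 0.05)
})

test_that("penalty norm of the estimate decreases as gamma grows", {
  sw <- withr::with_seed(5, {
    t <- 0.5 * (0:63)
    tibble::tibble(time = t,
                   amplitude = exp(-(t - 15)^2 / 20) + stats::rnorm(64, sd = 0.1))
  })
  ops <- build_operators(64, 1, 0.5)
  fn <- vapply(10^seq(-6, 6, by = 1), function(g) {
    est <- estimate_derivative(sw, sigma = 0.1, gamma = g, ops = ops)
    sqrt(sum((ops$F %*% est$u_hat)^2))
  }, numeric(1))
  expect_true(all(diff(fn) <= 1e-10 * max(fn)))
})

test_that("as gamma -> 0 the estimate approaches the unregularized inverse", {
  sw <- smooth_sweep(n = 32, dt = 0.5)
  est <- estimate_derivative(sw, sigma = 1, gamma = 1e-14)
  ops <- build_operators(32, 1, 0.5)
  u0 <- drop(forwardsolve(ops$G, sw$amplitude))
  expect_lt(max(abs(est$u_hat - u0)), 1e-4 * max(abs(u0)))
})

test_that("baseline sigma estimation recovers a known noise level", {
  sw <- withr::with_seed(21, {
    t <- 0.1 * (0:999)
    tibble::tibble(time = t, amplitude = stats::rnorm(1000, sd = 0.005))
  })
  nm <- estimate_sigma(sw, baseline_window = c(0, 50))
  expect_equal(nm$source, "estimated")
  expect_equal(nm$sigma, 0.005, tolerance = 0.15)
})

test_that("degenerate and undersized baselines are handled", {
  t <- 0.1 * (0:199)
  flat <- tibble::tibble(time = t, amplitude = rep(1, 200))
  expect_warning(nm <- estimate_sigma(flat, c(0, 10)),
                 class = "lfp_warning_degenerate_noise")
  expect_true(nm$degenerate)
  expect_gt(nm$sigma, 0)

  sw <- smooth_sweep(n = 200, dt = 0.1)
  expect_error(estimate_sigma(sw, c(0, 0.3)), class = "lfp_error_window")
})
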