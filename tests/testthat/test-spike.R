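test_that("alpha trace is zero before the spike and peaks kappa at tau", {
  expect_equal(alpha_trace(0, 2, 10), 0)
  expect_equal(alpha_trace(-5, 2, 10), 0)
  expect_equal(alpha_trace(10, 2, 10), 2)
  # derivative changes sign exactly at the peak time
  eps <- 1e-6
  expect_gt(alpha_trace(10, 1, 10) - alpha_trace(10 - eps, 1, 10), 0)
  expect_gt(alpha_trace(10, 1, 10) - alpha_trace(10 + eps, 1, 10), 0)
  t <- seq(0, 9.99, by = 0.01)
  expect_true(all(diff(alpha_trace(t, 1, 10)) > 0))
  expect_error(alpha_trace(1, 1, -2), "tau")
  expect_error(trace_params(0, 1, 1), "kappa")
})

test_that("closed forms match adaptive quadrature across regimes", {
  # spot-check grid; the exhaustive sweep lives in the acceptance suite
  dts <- c(-45, -12, -3, 0, 3, 12, 45)
  for (p in list(trace_params(1, 30, 20), trace_params(1, 20, 20),
                 trace_params(1, 15, 20))) {
    for (k in GDHL_COMPONENTS) {
      a <- spike_component_dw(k, dts, p)
      q <- spike_component_dw(k, dts, p, method = "quadrature")
      expect_equal(a, q, tolerance = 1e-9)
      expect_true(all(a >= 0)) # unit-coefficient kernels never depress
    }
  }
})

test_that("np and pn vanish exactly on the wrong-sign half line at equal tau", {
  p <- trace_params(1, 20, 20)
  expect_identical(spike_component_dw("np", seq(-60, 0, by = 5), p),
                   rep(0, 13))
  expect_identical(spike_component_dw("pn", seq(0, 60, by = 5), p),
                   rep(0, 13))
  # and are positive on their own half lines
  expect_true(all(spike_component_dw("np", c(5, 15, 40), p) > 0))
  expect_true(all(spike_component_dw("pn", c(-40, -15, -5), p) > 0))
})

test_that("component kernels are continuous across piecewise breakpoints", {
  eps <- 1e-7
  for (p in list(trace_params(1, 20, 20), trace_params(1, 30, 20))) {
    breaks <- c(0, p$tau1, -p$tau2, p$tau1 - p$tau2)
    for (k in GDHL_COMPONENTS) {
      lo <- spike_component_dw(k, breaks - eps, p)
      hi <- spike_component_dw(k, breaks + eps, p)
      expect_equal(lo, hi, tolerance = 1e-5)
    }
  }
})

test_that("kernel values scale as kappa squared", {
  for (k in c("pp", "sp", "ns", "nn")) {
    v1 <- spike_component_dw(k, c(-7, 4, 18), trace_params(1, 25, 15))
    v3 <- spike_component_dw(k, c(-7, 4, 18), trace_params(3, 25, 15))
    expect_equal(v3, 9 * v1, tolerance = 1e-12)
  }
})

test_that("component peaks sit where the theory says", {
  p <- trace_params(1, 20, 20)
  pk <- spike_kernel_peak("pp", p)
  expect_equal(pk$delta_t, 0, tolerance = 1e-6)
  # pp peaks at zero in unequal-tau regimes too
  expect_equal(spike_kernel_peak("pp", trace_params(1, 30, 20))$delta_t, 0,
               tolerance = 1e-6)
  # pn only acts for negative intervals, np for positive ones
  expect_lt(spike_kernel_peak("pn", p)$delta_t, 0)
  expect_gt(spike_kernel_peak("np", p)$delta_t, 0)
  # nn peak sign follows the tau ordering
  expect_gt(spike_kernel_peak("nn", trace_params(1, 30, 20))$delta_t, 0)
  expect_lt(spike_kernel_peak("nn", trace_params(1, 15, 20))$delta_t, 0)
  # golden-section result agrees with a brute-force grid search
  for (k in c("sp", "ns")) {
    pk <- spike_kernel_peak(k, p)
    grid <- seq(-200, 200, by = 0.05)
    vals <- spike_component_dw(k, grid, p)
    expect_equal(pk$dw, max(vals), tolerance = 1e-6)
    expect_equal(pk$delta_t, grid[which.max(vals)], tolerance = 0.1)
  }
})

test_that("analytic kernel is linear in coefficients and matches simulation", {
  p <- trace_params(1, 20, 20)
  dts <- seq(-60, 60, by = 10)
  zero <- spike_kernel(gdhl_coefficients(), p, dts)
  expect_equal(zero$dws, rep(0, length(dts)))
  cf <- gdhl_coefficients(eta_sp = 0.66, eta_ns = -0.6, sigma_pp = 0.2)
  k <- spike_kernel(cf, p, dts)
  manual <- 0.66 * spike_component_dw("sp", dts, p) -
    0.6 * spike_component_dw("ns", dts, p) +
    0.2 * spike_component_dw("pp", dts, p)
  expect_equal(k$dws, manual)
  # cross-check against step-by-step integration of sampled alpha traces
  dt <- 0.02
  t0 <- -150; n <- as.integer(round(400 / dt))
  t <- t0 + (seq_len(n) - 1) * dt
  for (d in c(-15, 0, 25)) {
    s1 <- signal(alpha_trace(t, 1, p$tau1), dt = dt, t0 = t0)
    s2 <- signal(alpha_trace(t - d, 1, p$tau2), dt = dt, t0 = t0)
    num <- gdhl_integrate(s1, s2, cf)$total_dw
    ana <- spike_kernel_values(cf, p, d)
    expect_equal(num, ana, tolerance = 5e-3)
  }
})
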