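test_that("positive/negative parts implement the rectifier pair", {
  expect_equal(positive_part(0.7), 0.7)
  expect_equal(positive_part(-0.5), 0)
  expect_equal(positive_part(0), 0)
  expect_equal(negative_part(-0.5), 0.5)
  expect_equal(negative_part(0.7), 0)
  # decomposition identity on a spread of values
  x <- seq(-3, 3, by = 0.17)
  expect_equal(positive_part(x) - negative_part(x), x)
  expect_true(all(positive_part(x) >= 0) && all(negative_part(x) >= 0))
  expect_error(positive_part(NaN), "finite")
  expect_error(negative_part(Inf), "finite")
})

test_that("signal constructor enforces its invariants", {
  expect_error(signal(1, dt = 0.1), "2 samples")
  expect_error(signal(c(1, NA), dt = 0.1), "finite")
  expect_error(signal(c(1, 2), dt = 0), "positive")
  s <- signal(c(0, 1, 4), dt = 0.5, t0 = 2)
  expect_equal(signal_times(s), c(2, 2.5, 3))
})

test_that("derivative uses central differences and matches cos(t) for sin(t)", {
  s_const <- signal(rep(3, 10), dt = 0.1)
  expect_equal(signal_derivative(s_const)$values, rep(0, 10))
  s_ramp <- fn_signal(function(t) 2 * t, n = 50)
  d <- signal_derivative(s_ramp)$values
  expect_equal(d[2:49], rep(2, 48))
  # closed-form oracle: d/dt sin = cos, second-order accurate interior
  s_sin <- fn_signal(sin, dt = 1e-3, n = 2001)
  d <- signal_derivative(s_sin)$values
  t <- signal_times(s_sin)
  err <- abs(d[2:2000] - cos(t[2:2000]))
  expect_lt(max(err), 1e-6) # O(dt^2) with dt = 1e-3
  expect_error(signal_derivative(signal(c(1, 2), dt = 1)), "3 samples")
})

test_that("cosine event peaks at the centre, vanishes at edges, is symmetric", {
  spec <- event_spec(0.5, 0.2, amplitude = 1.5)
  s <- cosine_event(spec, t0 = 0, dt = 1e-3, n = 1001)
  t <- signal_times(s)
  expect_equal(s$values[t == 0.5], 1.5)
  expect_equal(s$values[abs(t - 0.3) < 1e-9], 0)
  expect_equal(s$values[abs(t - 0.7) < 1e-9], 0)
  expect_true(all(s$values >= 0))
  # symmetry about the centre, sample by sample
  i0 <- which.min(abs(t - 0.5))
  k <- 1:200
  expect_equal(s$values[i0 - k], s$values[i0 + k], tolerance = 1e-12)
  expect_warning(cosine_event(spec, t0 = 0.45, dt = 1e-3, n = 100),
                 "truncated")
  expect_error(event_spec(0, -1), "half_width")
})

test_that("random mixtures are bounded, seeded and reproducible", {
  a <- random_cosine_mixture(4, c(0.1, 3), n = 2001, seed = 7)
  b <- random_cosine_mixture(4, c(0.1, 3), n = 2001, seed = 7)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= 0) && all(a$values <= 1))
  c2 <- random_cosine_mixture(4, c(0.1, 3), n = 2001, seed = 8)
  expect_false(identical(a$values, c2$values))
  expect_error(random_cosine_mixture(0, c(0.1, 3), n = 100, seed = 1),
               "n_components")
})

test_that("leaky trace follows the accumulator recursion and converges", {
  u <- signal(rep(1, 2001), dt = 0.001)
  m <- leaky_trace(u, tau = 1)
  # first step of the recursion with dt = 0.001, tau = 1
  expect_equal(m$values[2], 0.001)
  # monotone rise towards the constant input, bounded by it
  expect_true(all(diff(m$values) > 0))
  expect_true(all(m$values < 1))
  mc <- leaky_trace(signal(rep(0.7, 20001), dt = 0.01), tau = 0.2)
  expect_equal(mc$values[20001], 0.7, tolerance = 1e-6)
  # impulse decay follows the continuous-limit exponential
  imp <- signal(c(1, rep(0, 5000)), dt = 0.001)
  tr <- leaky_trace(imp, tau = 0.5, init = 0)
  # after the kick at step 2, decay over span T multiplies by ~exp(-T/tau)
  i0 <- 2L; i1 <- 3002L # T = 3 time units
  expect_equal(tr$values[i1] / tr$values[i0], exp(-3 / 0.5),
               tolerance = 1e-2)
  expect_error(leaky_trace(u, tau = 0), "tau")
})

test_that("shift_nonnegative only shifts when needed and keeps derivatives", {
  s_pos <- signal(c(0.2, 0.5, 0.1), dt = 1)
  expect_identical(shift_nonnegative(s_pos), s_pos)
  s_neg <- signal(c(-2, 1, 0), dt = 1)
  sh <- shift_nonnegative(s_neg)
  expect_equal(min(sh$values), 0)
  expect_equal(signal_derivative(sh)$values, signal_derivative(s_neg)$values)
})

test_that("signal CSV round-trips through the time,value dialect", {
  s <- fn_signal(function(t) sin(3 * t) + 1, dt = 0.01, n = 101)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(s, path, comment = "round-trip check")
  r <- read_signal_csv(path)
  expect_equal(r$values, s$values, tolerance = 1e-10)
  expect_equal(r$dt, s$dt, tolerance = 1e-10)
  expect_equal(r$t0, s$t0)
})
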