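test_that("presets reproduce the published coefficient patterns", {
  k <- gdhl_preset("kosko")$weights
  expect_equal(unname(k[c("pp", "pn", "np", "nn")]), c(1, -1, -1, 1))
  expect_equal(unname(k[c("sp", "sn", "ps", "ns")]), c(0, 0, 0, 0))
  pw <- gdhl_preset("porr_worgotter", lambda = 2.5)$weights
  expect_equal(unname(pw[c("sp", "sn")]), c(2.5, -2.5))
  expect_equal(sum(abs(pw[c("pp", "pn", "np", "nn", "ps", "ns")])), 0)
  fz <- gdhl_preset("flat_at_zero")$weights
  expect_equal(unname(fz[c("pn", "np")]), c(-1, 1))
  ac <- gdhl_preset("anticausal")$weights
  expect_equal(unname(ac[c("sn", "ns")]), c(1, -1))
  hb <- gdhl_preset("hebb")$weights
  expect_equal(unname(hb[c("pp", "nn")]), c(1, 1))
  expect_error(gdhl_preset("nope"))
})

test_that("component products are unsigned terms that sum to the rule", {
  expect_equal(component_product("pp", 1, 2, 1, 3), 6)
  expect_equal(component_product("ps", 1, -1, 5, 1), 0) # [du1]+ = 0
  expect_equal(component_product("sp", 2, 0, 3, 4), 8)  # u1 * [du2]+
  expect_error(component_product("ss", 1, 1, 1, 1), "unknown")
  # linearity: Kosko-signed sum of products reproduces the full update
  set.seed(3)
  u1 <- runif(20); du1 <- rnorm(20); u2 <- runif(20); du2 <- rnorm(20)
  signs <- c(pp = 1, pn = -1, np = -1, nn = 1, sp = 0, sn = 0, ps = 0, ns = 0)
  manual <- Reduce(`+`, lapply(GDHL_COMPONENTS, function(k) {
    signs[[k]] * component_product(k, u1, du1, u2, du2)
  }))
  expect_equal(gdhl_update(u1, du1, u2, du2, gdhl_preset("kosko")), manual)
})

test_that("Kosko and Porr-Wörgötter presets equal their product forms", {
  s1 <- random_cosine_mixture(4, c(0.1, 3), n = 2001, seed = 31)
  s2 <- random_cosine_mixture(4, c(0.1, 3), n = 2001, seed = 32)
  du1 <- signal_derivative(s1)$values
  du2 <- signal_derivative(s2)$values
  wk <- gdhl_update(s1$values, du1, s2$values, du2, gdhl_preset("kosko"))
  expect_equal(max(abs(wk - du1 * du2)), 0)
  wp <- gdhl_update(s1$values, du1, s2$values, du2,
                    gdhl_preset("porr_worgotter", lambda = 1.7))
  expect_equal(max(abs(wp - 1.7 * s1$values * du2)), 0)
})

test_that("the update is linear in coefficients and zero when they are", {
  u1 <- c(0.5, 1); du1 <- c(0.3, -0.2); u2 <- c(0.1, 0.9); du2 <- c(-1, 2)
  zero <- gdhl_coefficients()
  expect_equal(gdhl_update(u1, du1, u2, du2, zero), c(0, 0))
  a <- gdhl_coefficients(sigma_pp = 0.4, eta_sn = -1.2)
  b <- gdhl_coefficients(sigma_nn = 2, eta_ps = 0.5)
  ab <- gdhl_coefficients(sigma_pp = 0.4, eta_sn = -1.2, sigma_nn = 2,
                          eta_ps = 0.5)
  expect_equal(gdhl_update(u1, du1, u2, du2, ab),
               gdhl_update(u1, du1, u2, du2, a) +
                 gdhl_update(u1, du1, u2, du2, b))
  expect_error(gdhl_update(-0.1, 0, 1, 0, a), "nonnegative")
})

test_that("integration accumulates Euler steps and handles event overlap", {
  # disjoint events: every product term vanishes, total exactly zero
  s1 <- cosine_event(event_spec(0.5, 0.2), t0 = 0, dt = 1e-3, n = 3001)
  s2 <- cosine_event(event_spec(2.0, 0.2), t0 = 0, dt = 1e-3, n = 3001)
  traj <- gdhl_integrate(s1, s2, gdhl_preset("kosko"))
  expect_equal(traj$total_dw, 0)
  # running sum invariant
  expect_equal(traj$w, cumsum(traj$wdot) * traj$dt)
  # identical overlapping events, Porr-Wörgötter: int u * du dt = 0
  trj2 <- gdhl_integrate(s1, s1, gdhl_preset("porr_worgotter"))
  expect_lt(abs(trj2$total_dw), 1e-9)
  expect_error(gdhl_integrate(s1, signal(s2$values[1:100], 1e-3), gdhl_preset("kosko")),
               "grid")
})

test_that("coincidence rule is maximal for synchronous events", {
  spec <- event_spec(0, 0.2)
  k <- numerical_kernel(spec, gdhl_preset("coincidence"),
                        delta_ts = seq(-0.6, 0.6, by = 0.05))
  expect_equal(k$delta_ts[which.max(k$dws)], 0)
  expect_gt(max(k$dws), 0)
})

test_that("total weight change is invariant to a common time shift", {
  spec1 <- event_spec(0.6, 0.2)
  spec2 <- event_spec(0.75, 0.2)
  n <- 3001
  a1 <- cosine_event(spec1, t0 = 0, dt = 1e-3, n = n)
  a2 <- cosine_event(spec2, t0 = 0, dt = 1e-3, n = n)
  b1 <- cosine_event(event_spec(1.4, 0.2), t0 = 0, dt = 1e-3, n = n)
  b2 <- cosine_event(event_spec(1.55, 0.2), t0 = 0, dt = 1e-3, n = n)
  for (p in c("kosko", "causal", "coincidence", "anticausal")) {
    expect_equal(gdhl_integrate(a1, a2, gdhl_preset(p))$total_dw,
                 gdhl_integrate(b1, b2, gdhl_preset(p))$total_dw,
                 tolerance = 1e-9)
  }
})

test_that("coefficients serialise to flat JSON and back", {
  cf <- gdhl_coefficients(sigma_pp = 0.73, eta_ps = -0.025, rate = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_coefficients_json(cf, path)
  r <- read_coefficients_json(path)
  expect_equal(r$weights, cf$weights)
  expect_equal(r$rate, 2)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"sigma_pp": 1}', bad)
  expect_error(read_coefficients_json(bad), "missing keys")
})
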