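# shared fixtures: all built in code at test time

# a short uniform grid signal from a function of time
fn_signal <- function(f, t0 = 0, dt = 1e-3, n = 1001) {
  t <- t0 + (seq_len(n) - 1) * dt
  signal(f(t), dt = dt, t0 = t0)
}

# small GA budget for tests; the 2D (tau1, tau2) search plus the local
# polish keeps subset fits near their optima at this size
test_ga <- function(seed = 1, ...) {
  ga_config(population = 12, generations = 8, restarts = 1, seed = seed, ...)
}

# the standard recovery truth: 2 mixed components, equal trace constants
recovery_spec <- function(seed, noise_sd = 0.05, n_points = 60) {
  synthetic_spec(gdhl_coefficients(eta_sp = 0.66, eta_ns = -0.60),
                 trace_params(1, 20, 20), n_points = n_points,
                 delta_t_range = c(-100, 100), noise_sd = noise_sd,
                 seed = seed)
}
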