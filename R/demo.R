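#' Pre-filtering demonstration on random mixture signals
#'
#' Reproduces the canonical pre-filtering experiment: two independent
#' random cosine-mixture signals are filtered with the rise detector
#' `positive_part(du)` and/or the fall detector `negative_part(du)`, and a
#' differential Hebbian rule is then integrated over the filtered signals.
#' Detecting rises in both signals versus rises in one and falls in the
#' other yields systematically opposite weight drifts: the choice of filter
#' decides *which* events the rule relates, and thereby the sign of
#' learning.
#'
#' @param seed Integer seed; the two mixtures use sub-seeds `2*seed` and
#'   `2*seed + 1`.
#' @param filter_pre,filter_post `"rise"`, `"fall"` or `"none"` (use the
#'   raw signal).
#' @param coefficients Rule applied to the filtered signals (default the
#'   Porr-Wörgötter preset).
#' @param duration Signal duration (time units).
#' @param dt Sampling step.
#' @param n_components,freq_range Passed to [random_cosine_mixture()].
#' @return List with elements `trajectory` (a `gdhl_trajectory`),
#'   `total_dw`, and the two filtered signals `v1`, `v2`.
#' @export
simulate_filtered_pair <- function(seed = 1, filter_pre = "rise",
                                   filter_post = "rise",
                                   coefficients = gdhl_preset("porr_worgotter"),
                                   duration = 10, dt = 0.001,
                                   n_components = 4,
                                   freq_range = c(0.1, 3)) {
  n <- as.integer(round(duration / dt)) + 1L
  u1 <- random_cosine_mixture(n_components, freq_range, t0 = 0, dt = dt,
                              n = n, seed = 2L * as.integer(seed))
  u2 <- random_cosine_mixture(n_components, freq_range, t0 = 0, dt = dt,
                              n = n, seed = 2L * as.integer(seed) + 1L)
  apply_filter <- function(s, which) {
    switch(which,
      none = s,
      rise = signal(positive_part(signal_derivative(s)$values),
                    dt = s$dt, t0 = s$t0),
      fall = signal(negative_part(signal_derivative(s)$values),
                    dt = s$dt, t0 = s$t0),
      stop(sprintf("unknown filter '%s'", which), call. = FALSE))
  }
  v1 <- apply_filter(u1, filter_pre)
  v2 <- apply_filter(u2, filter_post)
  traj <- gdhl_integrate(v1, v2, coefficients)
  list(trajectory = traj, total_dw = traj$total_dw, v1 = v1, v2 = v2)
}

#' Eligibility-trace demonstration with gap-separated events
#'
#' Two raised-cosine events separated by a silent gap. Applied directly to
#' the signals, any differential Hebbian rule yields exactly zero total
#' weight change (the events never overlap, so every product term
#' vanishes). Applied to their leaky-integrator traces, the memory of the
#' first event overlaps the second and the rule registers their temporal
#' order.
#'
#' @param use_traces Integrate the rule over the leaky traces instead of
#'   the raw signals.
#' @param tau Trace time constant (time units).
#' @param gap Silent interval between the end of the first event and the
#'   start of the second.
#' @param half_width Event half width.
#' @param coefficients Rule (default the single `sp` component
#'   u1 * positive_part(du2)).
#' @param dt Sampling step.
#' @return List with `total_dw`, the `trajectory`, and the two integrated
#'   signals `s1`, `s2` (traces when `use_traces`).
#' @export
gap_trace_demo <- function(use_traces = FALSE, tau = 1, gap = 0.5,
                           half_width = 0.5,
                           coefficients = gdhl_coefficients(eta_sp = 1),
                           dt = 0.001) {
  c1 <- half_width + 0.25
  c2 <- c1 + 2 * half_width + gap
  t_end <- c2 + half_width + 6 * tau # let the traces decay out
  n <- as.integer(round(t_end / dt)) + 1L
  s1 <- cosine_event(event_spec(c1, half_width), t0 = 0, dt = dt, n = n)
  s2 <- cosine_event(event_spec(c2, half_width), t0 = 0, dt = dt, n = n)
  if (use_traces) {
    s1 <- leaky_trace(s1, tau)
    s2 <- leaky_trace(s2, tau)
  }
  traj <- gdhl_integrate(s1, s2, coefficients)
  list(total_dw = traj$total_dw, trajectory = traj, s1 = s1, s2 = s2)
}
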