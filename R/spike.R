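#' Eligibility-trace parameters for spike-pair analysis
#'
#' A pre/post spike pair is modelled as two Dirac impulses whose traces are
#' alpha functions: the pre spike (at time 0) leaves a trace with time
#' constant `tau1`, the post spike (at time Delta_t) one with `tau2`, both
#' peaking at amplitude `kappa`.
#'
#' @param kappa Trace peak amplitude, > 0 (dimensionless; every kernel value
#'   scales as kappa^2).
#' @param tau1 Pre-synaptic trace time constant (ms), > 0.
#' @param tau2 Post-synaptic trace time constant (ms), > 0.
#' @return An object of class `trace_params`.
#' @export
trace_params <- function(kappa = 1, tau1, tau2) {
  if (!is.finite(kappa) || kappa <= 0) stop("`kappa` must be > 0", call. = FALSE)
  if (!is.finite(tau1) || tau1 <= 0) stop("`tau1` must be > 0", call. = FALSE)
  if (!is.finite(tau2) || tau2 <= 0) stop("`tau2` must be > 0", call. = FALSE)
  structure(list(kappa = kappa, tau1 = tau1, tau2 = tau2),
            class = "trace_params")
}

#' @export
print.trace_params <- function(x, ...) {
  cat(sprintf("<trace_params> kappa = %g, tau1 = %g, tau2 = %g\n",
              x$kappa, x$tau1, x$tau2))
  invisible(x)
}

#' Alpha-function trace
#'
#' eps(t) = kappa * (t/tau) * exp(1 - t/tau) for t >= 0 and 0 before the
#' spike; normalised so the peak value is exactly `kappa`, reached at
#' t = tau. Its derivative is positive on (0, tau) and negative afterwards —
#' these two lobes are the `p` and `n` factors of the spike-pair components.
#'
#' @param t Time since the spike (vectorised).
#' @param kappa Peak amplitude.
#' @param tau Time constant, > 0.
#' @return Nonnegative numeric vector.
#' @export
alpha_trace <- function(t, kappa = 1, tau) {
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  ifelse(t >= 0, kappa * (t / tau) * exp(1 - t / tau), 0)
}

# Factor description for one trace letter: support (a, b) and linear
# polynomial p0 + p1 * t multiplying exp(-t / tau), for a spike at t = 0.
#   s: the trace itself, (kappa e / tau) * t on (0, Inf)
#   p: its derivative's positive lobe, (kappa e / tau)(1 - t/tau) on (0, tau)
#   n: the negative lobe's magnitude, (kappa e / tau)(t/tau - 1) on (tau, Inf)
.spike_factor <- function(letter, kappa, tau) {
  ke <- kappa * exp(1) / tau
  switch(letter,
    s = list(a = 0, b = Inf, p0 = 0, p1 = ke),
    p = list(a = 0, b = tau, p0 = ke, p1 = -ke / tau),
    n = list(a = tau, b = Inf, p0 = -ke, p1 = ke / tau))
}

# Exact integral of (q0 + q1 t + q2 t^2) * exp(cc - lambda t) over (L, U),
# vectorised; U may be Inf. cc - lambda * t <= 0 over the domain for every
# spike-pair component, so no overflow can occur.
.poly_exp_integral <- function(q0, q1, q2, cc, lambda, L, U) {
  antider <- function(t) {
    # value 0 at t = Inf
    out <- numeric(length(t))
    fin <- is.finite(t)
    tf <- t[fin]
    out[fin] <- -exp(cc[fin] - lambda * tf) *
      (q0[fin] / lambda +
       q1[fin] * (tf / lambda + 1 / lambda^2) +
       q2[fin] * (tf^2 / lambda + 2 * tf / lambda^2 + 2 / lambda^3))
    out
  }
  val <- antider(U) - antider(L)
  ifelse(U > L, val, 0)
}

#' Closed-form spike-pair component kernel
#'
#' Total weight change produced by one unsigned rule component for a pre
#' spike at 0 and a post spike at Delta_t, with alpha-function traces:
#' the definite integral of the component product of the two trace factors,
#' evaluated in closed form. After expanding the product, every component
#' integrand is a quadratic polynomial times exp(Delta_t/tau2 - lambda t)
#' with combined decay lambda = 1/tau1 + 1/tau2 over a single interval (the
#' overlap of the two factor supports, with breakpoints at 0, Delta_t and
#' the trace peak times), so the antiderivative is exact for all tau1, tau2
#' including tau1 == tau2. `method = "quadrature"` computes the same
#' integral by adaptive numerical quadrature instead and serves as an
#' independent cross-check of the closed form.
#'
#' @param component One of [GDHL_COMPONENTS].
#' @param delta_t Inter-spike interval(s), ms; t_post - t_pre.
#' @param params A [trace_params()].
#' @param method `"closed_form"` (default) or `"quadrature"`.
#' @return Nonnegative numeric vector, one value per delay.
#' @examples
#' p <- trace_params(1, 20, 20)
#' spike_component_dw("pp", c(-10, 0, 10), p)
#' @export
spike_component_dw <- function(component, delta_t, params,
                               method = c("closed_form", "quadrature")) {
  stopifnot(inherits(params, "trace_params"))
  method <- match.arg(method)
  if (!component %in% GDHL_COMPONENTS) {
    stop(sprintf("unknown component '%s'", component), call. = FALSE)
  }
  if (!all(is.finite(delta_t))) stop("`delta_t` must be finite", call. = FALSE)
  f1 <- .spike_factor(substr(component, 1L, 1L), params$kappa, params$tau1)
  f2 <- .spike_factor(substr(component, 2L, 2L), params$kappa, params$tau2)
  L <- pmax(f1$a, delta_t + f2$a)
  U <- pmin(f1$b, delta_t + f2$b)
  if (method == "quadrature") {
    return(.spike_quadrature(f1, f2, params, delta_t, L, U))
  }
  lambda <- 1 / params$tau1 + 1 / params$tau2
  # post factor polynomial re-expressed in t: p20 + p21 (t - delta_t)
  r0 <- f2$p0 - f2$p1 * delta_t
  r1 <- rep(f2$p1, length(delta_t))
  q0 <- f1$p0 * r0
  q1 <- f1$p0 * r1 + f1$p1 * r0
  q2 <- f1$p1 * r1
  cc <- delta_t / params$tau2
  .poly_exp_integral(q0, q1, q2, cc, lambda, L, U)
}

# Independent oracle for spike_component_dw: pointwise integrand +
# stats::integrate, split at the interior breakpoints (the trace peak
# times) where the integrand has kinks.
.spike_quadrature <- function(f1, f2, params, delta_t, L, U) {
  integrand <- function(t, d) {
    g1 <- ifelse(t > f1$a & t < f1$b,
                 (f1$p0 + f1$p1 * t) * exp(-t / params$tau1), 0)
    s <- t - d
    g2 <- ifelse(s > f2$a & s < f2$b,
                 (f2$p0 + f2$p1 * s) * exp(-s / params$tau2), 0)
    g1 * g2
  }
  vapply(seq_along(delta_t), function(i) {
    lo <- L[i]; hi <- U[i]
    if (hi <= lo) return(0)
    # truncate the infinite tail where both exponentials are ~1e-140 down
    if (!is.finite(hi)) {
      hi <- lo + 650 / (1 / params$tau1 + 1 / params$tau2) +
        10 * max(params$tau1, params$tau2)
    }
    knots <- sort(unique(c(lo, hi,
                           params$tau1,
                           delta_t[i] + params$tau2)))
    knots <- knots[knots >= lo & knots <= hi]
    tot <- 0
    for (j in seq_len(length(knots) - 1L)) {
      tot <- tot + stats::integrate(integrand, knots[j], knots[j + 1L],
                                    d = delta_t[i], rel.tol = 1e-12,
                                    abs.tol = 0,
                                    subdivisions = 400L)$value
    }
    tot
  }, numeric(1))
}

#' Analytic spike-pair learning kernel
#'
#' Coefficient-weighted sum of the eight closed-form component kernels,
#' times the global rate: the phenomenological Delta_w = f(Delta_t) curve
#' implied by a coefficient set under alpha-function traces.
#'
#' @param coefficients A [gdhl_coefficients()].
#' @param params A [trace_params()].
#' @param delta_ts Delay grid (ms), strictly increasing.
#' @return A [kernel_curve()].
#' @examples
#' spike_kernel(gdhl_coefficients(eta_sp = 0.66, eta_ns = -0.6),
#'              trace_params(1, 20, 20), seq(-100, 100, 5))
#' @export
spike_kernel <- function(coefficients, params, delta_ts) {
  stopifnot(inherits(coefficients, "gdhl_coefficients"))
  dws <- spike_kernel_values(coefficients, params, delta_ts)
  kernel_curve(delta_ts, dws)
}

#' @rdname spike_kernel
#' @return `spike_kernel_values()` returns the bare numeric vector (no
#'   monotone-delay requirement), convenient for prediction at observed
#'   data points.
#' @export
spike_kernel_values <- function(coefficients, params, delta_ts) {
  stopifnot(inherits(coefficients, "gdhl_coefficients"))
  w <- coefficients$weights
  acc <- numeric(length(delta_ts))
  for (k in GDHL_COMPONENTS) {
    if (w[[k]] != 0) {
      acc <- acc + w[[k]] * spike_component_dw(k, delta_ts, params)
    }
  }
  coefficients$rate * acc
}

#' Peak of a spike-pair component kernel
#'
#' Argmax and maximum of the unit-coefficient component kernel over the
#' inter-spike interval, located by a coarse grid scan refined with
#' golden-section search ([stats::optimize()]) between the bracketing grid
#' neighbours.
#'
#' @param component One of [GDHL_COMPONENTS].
#' @param params A [trace_params()].
#' @return List with `delta_t`, `dw` and `method = "golden-section"`.
#' @export
spike_kernel_peak <- function(component, params) {
  stopifnot(inherits(params, "trace_params"))
  span <- 10 * (params$tau1 + params$tau2)
  grid <- seq(-span, span, length.out = 801L)
  vals <- spike_component_dw(component, grid, params)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(d) spike_component_dw(component, d, params),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-10)
  list(delta_t = opt$maximum, dw = opt$objective, method = "golden-section")
}
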