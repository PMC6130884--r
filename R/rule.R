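#' The eight G-DHL component identifiers
#'
#' Two-letter codes: the first letter names the pre-synaptic factor, the
#' second the post-synaptic one; `s` is the signal u_i itself, `p` the
#' positive part of its derivative, `n` the (magnitude of the) negative
#' part. The signal-by-signal combination `ss` is excluded: it reproduces
#' the plain Hebb rule already covered by `pp` + `nn`.
#'
#' @format Character vector of length 8.
#' @export
GDHL_COMPONENTS <- c("pp", "pn", "np", "nn", "sp", "sn", "ps", "ns")

#' G-DHL rule coefficients
#'
#' One weight per rule component — four differential weights `sigma_*`
#' (derivative x derivative) and four mixed weights `eta_*` (signal x
#' derivative) — plus a global positive learning-rate multiplier applied to
#' the sum. The sign of a weight decides whether its component potentiates
#' (LTP) or depresses (LTD) the synapse; the magnitude weights its
#' contribution. The coefficient vector fully determines a differential
#' Hebbian rule.
#'
#' @param sigma_pp,sigma_pn,sigma_np,sigma_nn Differential component weights.
#' @param eta_sp,eta_sn,eta_ps,eta_ns Mixed component weights.
#' @param rate Global multiplier (the 1/tau of the classic rate formulations),
#'   > 0, default 1.
#' @return An object of class `gdhl_coefficients`.
#' @examples
#' gdhl_preset("kosko")
#' gdhl_coefficients(eta_sp = 0.66, eta_ns = -0.60)
#' @export
gdhl_coefficients <- function(sigma_pp = 0, sigma_pn = 0, sigma_np = 0,
                              sigma_nn = 0, eta_sp = 0, eta_sn = 0,
                              eta_ps = 0, eta_ns = 0, rate = 1) {
  v <- c(pp = sigma_pp, pn = sigma_pn, np = sigma_np, nn = sigma_nn,
         sp = eta_sp, sn = eta_sn, ps = eta_ps, ns = eta_ns)
  if (!all(is.finite(v))) stop("coefficients must be finite", call. = FALSE)
  if (!is.finite(rate) || rate <= 0) stop("`rate` must be > 0", call. = FALSE)
  structure(list(weights = v[GDHL_COMPONENTS], rate = as.numeric(rate)),
            class = "gdhl_coefficients")
}

#' @export
print.gdhl_coefficients <- function(x, ...) {
  cat("<gdhl_coefficients>\n")
  w <- x$weights
  cat(sprintf("  sigma: pp=%g pn=%g np=%g nn=%g\n",
              w["pp"], w["pn"], w["np"], w["nn"]))
  cat(sprintf("  eta:   sp=%g sn=%g ps=%g ns=%g\n",
              w["sp"], w["sn"], w["ps"], w["ns"]))
  cat(sprintf("  rate:  %g\n", x$rate))
  invisible(x)
}

#' Named rule presets
#'
#' Classic differential Hebbian rules expressed as G-DHL coefficient sets:
#' `kosko` (derivative x derivative, sign pattern + - - +, equal to
#' du1 * du2), `porr_worgotter` (lambda * u1 * du2 through sp/sn), `hebb`
#' (the symmetric rule recovered from the pp and nn components), and the
#' four demonstration rules `causal`, `anticausal`, `coincidence` and
#' `flat_at_zero`.
#'
#' @param name Preset name.
#' @param lambda Scale of the Porr-Wörgötter preset (default 1).
#' @param rate Global rate multiplier passed through.
#' @return A [gdhl_coefficients()] object.
#' @export
gdhl_preset <- function(name = c("hebb", "kosko", "porr_worgotter", "causal",
                                 "anticausal", "coincidence", "flat_at_zero"),
                        lambda = 1, rate = 1) {
  name <- match.arg(name)
  switch(name,
    hebb = gdhl_coefficients(sigma_pp = 1, sigma_nn = 1, rate = rate),
    kosko = gdhl_coefficients(sigma_pp = 1, sigma_pn = -1, sigma_np = -1,
                              sigma_nn = 1, rate = rate),
    porr_worgotter = gdhl_coefficients(eta_sp = lambda, eta_sn = -lambda,
                                       rate = rate),
    causal = gdhl_coefficients(eta_sp = 1, eta_sn = -1, rate = rate),
    anticausal = gdhl_coefficients(eta_sn = 1, eta_ns = -1, rate = rate),
    coincidence = gdhl_coefficients(sigma_pp = 1, sigma_nn = 1,
                                    sigma_pn = -1, sigma_np = -1,
                                    rate = rate),
    flat_at_zero = gdhl_coefficients(sigma_pn = -1, sigma_np = 1,
                                     rate = rate)
  )
}

#' Single unsigned rule component
#'
#' The raw product of one component, coefficient excluded: e.g. `"pn"` is
#' `positive_part(du1) * negative_part(du2)` and `"sp"` is
#' `u1 * positive_part(du2)`. [gdhl_update()] is the coefficient-weighted
#' sum of these eight products.
#'
#' @param component One of [GDHL_COMPONENTS].
#' @param u1,du1 Pre-synaptic activation and its derivative.
#' @param u2,du2 Post-synaptic activation and its derivative.
#' @return Nonnegative numeric vector.
#' @export
component_product <- function(component, u1, du1, u2, du2) {
  if (!component %in% GDHL_COMPONENTS) {
    stop(sprintf("unknown component '%s'", component), call. = FALSE)
  }
  fac <- function(letter, u, du) {
    switch(letter, s = u, p = positive_part(du), n = negative_part(du))
  }
  fac(substr(component, 1L, 1L), u1, du1) *
    fac(substr(component, 2L, 2L), u2, du2)
}

#' Instantaneous G-DHL weight change
#'
#' The core rule: the instantaneous synaptic change is the coefficient-
#' weighted sum of the eight products combining the pre-synaptic elements
#' \{u1, \[du1\]+, \[du1\]-\} with the post-synaptic elements
#' \{u2, \[du2\]+, \[du2\]-\} (the signal-by-signal product excluded),
#' all multiplied by the global rate.
#'
#' @param u1,du1,u2,du2 Activations (must be >= 0; pre-process with
#'   [shift_nonnegative()] if needed) and their derivatives. Vectorised.
#' @param coefficients A [gdhl_coefficients()].
#' @return Numeric vector of instantaneous weight changes (wdot).
#' @export
gdhl_update <- function(u1, du1, u2, du2, coefficients) {
  stopifnot(inherits(coefficients, "gdhl_coefficients"))
  if (any(u1 < 0) || any(u2 < 0)) {
    stop("activations must be nonnegative; see shift_nonnegative()",
         call. = FALSE)
  }
  w <- coefficients$weights
  p1 <- positive_part(du1); n1 <- negative_part(du1)
  p2 <- positive_part(du2); n2 <- negative_part(du2)
  coefficients$rate * (
    w[["pp"]] * p1 * p2 + w[["pn"]] * p1 * n2 +
    w[["np"]] * n1 * p2 + w[["nn"]] * n1 * n2 +
    w[["sp"]] * u1 * p2 + w[["sn"]] * u1 * n2 +
    w[["ps"]] * p1 * u2 + w[["ns"]] * n1 * u2)
}

#' Integrate the rule along a pair of signals
#'
#' Applies [gdhl_update()] sample by sample to two signals sharing a grid
#' (derivatives via [signal_derivative()]) and accumulates the weight by
#' explicit Euler: w_i = w0 + sum_{j<=i} wdot_j * dt. The total weight
#' change over the window is the learning-kernel value for this signal
#' pair.
#'
#' @param s1,s2 Pre- and post-synaptic [signal()]s on the same grid.
#' @param coefficients A [gdhl_coefficients()].
#' @param w0 Initial weight.
#' @return An object of class `gdhl_trajectory`: list with `t0`, `dt`,
#'   `wdot`, `w` and `total_dw`.
#' @export
gdhl_integrate <- function(s1, s2, coefficients, w0 = 0) {
  stopifnot(inherits(s1, "gdhl_signal"), inherits(s2, "gdhl_signal"))
  if (!.same_grid(s1, s2)) {
    stop("`s1` and `s2` must share the same grid", call. = FALSE)
  }
  du1 <- signal_derivative(s1)$values
  du2 <- signal_derivative(s2)$values
  wdot <- gdhl_update(s1$values, du1, s2$values, du2, coefficients)
  w <- w0 + cumsum(wdot) * s1$dt
  structure(list(t0 = s1$t0, dt = s1$dt, wdot = wdot, w = w,
                 total_dw = w[length(w)] - w0),
            class = "gdhl_trajectory")
}

#' @export
print.gdhl_trajectory <- function(x, ...) {
  cat(sprintf("<gdhl_trajectory> %d steps, dt = %g, total_dw = %.6g\n",
              length(x$w), x$dt, x$total_dw))
  invisible(x)
}

#' Serialise coefficients to / from JSON
#'
#' Flat JSON object with the eight component keys (`sigma_pp`, ...,
#' `eta_ns`) plus `rate`.
#'
#' @param coefficients A [gdhl_coefficients()].
#' @param path File path.
#' @return `write_coefficients_json()` returns `path` invisibly;
#'   `read_coefficients_json()` returns a `gdhl_coefficients`.
#' @export
write_coefficients_json <- function(coefficients, path) {
  stopifnot(inherits(coefficients, "gdhl_coefficients"))
  w <- coefficients$weights
  obj <- list(sigma_pp = w[["pp"]], sigma_pn = w[["pn"]],
              sigma_np = w[["np"]], sigma_nn = w[["nn"]],
              eta_sp = w[["sp"]], eta_sn = w[["sn"]],
              eta_ps = w[["ps"]], eta_ns = w[["ns"]],
              rate = coefficients$rate)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coefficients_json
#' @export
read_coefficients_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("sigma_pp", "sigma_pn", "sigma_np", "sigma_nn",
            "eta_sp", "eta_sn", "eta_ps", "eta_ns")
  missing <- setdiff(need, names(obj))
  if (length(missing)) {
    stop("coefficient JSON missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  do.call(gdhl_coefficients,
          c(obj[need], list(rate = if (is.null(obj$rate)) 1 else obj$rate)))
}
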