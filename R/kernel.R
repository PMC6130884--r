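#' Learning-kernel curve
#'
#' A learning kernel maps the inter-event delay Delta_t to the total weight
#' change Delta_w it produces. Convention used throughout the package:
#' Delta_t = t_post - t_pre, so positive delays mean the pre-synaptic event
#' leads.
#'
#' @param delta_ts Strictly increasing numeric vector of delays.
#' @param dws Weight changes, same length.
#' @return An object of class `kernel_curve`.
#' @export
kernel_curve <- function(delta_ts, dws) {
  delta_ts <- as.numeric(delta_ts)
  dws <- as.numeric(dws)
  if (length(delta_ts) != length(dws)) {
    stop("`delta_ts` and `dws` must have equal length", call. = FALSE)
  }
  if (any(diff(delta_ts) <= 0)) {
    stop("`delta_ts` must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(delta_ts)) || !all(is.finite(dws))) {
    stop("kernel values must be finite", call. = FALSE)
  }
  structure(list(delta_ts = delta_ts, dws = dws), class = "kernel_curve")
}

#' @export
print.kernel_curve <- function(x, ...) {
  i <- which.max(abs(x$dws))
  cat(sprintf(
    "<kernel_curve> %d delays in [%g, %g]; extreme dw = %.6g at dt = %g\n",
    length(x$delta_ts), min(x$delta_ts), max(x$delta_ts),
    x$dws[i], x$delta_ts[i]))
  invisible(x)
}

# Grid and event placement shared by the numerical-kernel routines: pre event
# centred at 0, post at delta_t; window is the union of the two supports
# padded by one full event width so the integrand is exactly zero at (and
# beyond) both ends.
.kernel_pair <- function(spec, delta_t, dt) {
  hw <- spec$half_width
  pad <- 2 * hw
  lo <- min(-hw, delta_t - hw) - pad
  hi <- max(hw, delta_t + hw) + pad
  n <- ceiling((hi - lo) / dt) + 1L
  pre <- cosine_event(spec, t0 = lo, dt = dt, n = n)
  post <- cosine_event(event_spec(spec$center + delta_t, hw, spec$amplitude),
                       t0 = lo, dt = dt, n = n)
  list(pre = pre, post = post)
}

#' Numerical learning kernel for an event waveform
#'
#' For each delay, places one copy of the event in the pre-synaptic signal
#' (peak at 0) and one in the post-synaptic signal (peak at Delta_t),
#' integrates the rule over a window covering both events, and records the
#' total weight change.
#'
#' @param spec An [event_spec()] (its `center` is taken as the pre event
#'   peak; the post event is the same waveform shifted by each delay).
#' @param coefficients A [gdhl_coefficients()].
#' @param delta_ts Delay grid (default \[-1, 1\] step 0.01).
#' @param dt Integration step (default 0.001).
#' @return A [kernel_curve()].
#' @examples
#' k <- numerical_kernel(event_spec(0, 0.2), gdhl_preset("causal"),
#'                       delta_ts = seq(-1, 1, 0.05))
#' k
#' @export
numerical_kernel <- function(spec, coefficients,
                             delta_ts = seq(-1, 1, by = 0.01), dt = 0.001) {
  stopifnot(inherits(spec, "event_spec"),
            inherits(coefficients, "gdhl_coefficients"))
  dws <- vapply(delta_ts, function(d) {
    pair <- .kernel_pair(spec, d, dt)
    gdhl_integrate(pair$pre, pair$post, coefficients)$total_dw
  }, numeric(1))
  kernel_curve(delta_ts, dws)
}

#' Per-component numerical kernels
#'
#' One kernel per rule component, each with unit coefficient, so any preset
#' kernel is recovered as the coefficient-weighted sum of these curves. With
#' a symmetric event the ps/sn pair coincides and so does sp/ns; with an
#' asymmetric event all eight curves are distinct.
#'
#' @inheritParams numerical_kernel
#' @return Named list of [kernel_curve()]s, one per [GDHL_COMPONENTS] entry.
#' @export
component_kernels <- function(spec, delta_ts = seq(-1, 1, by = 0.01),
                              dt = 0.001) {
  stopifnot(inherits(spec, "event_spec"))
  # integrate each component product once per delay, sharing the signal pair
  out <- lapply(GDHL_COMPONENTS, function(k) numeric(length(delta_ts)))
  names(out) <- GDHL_COMPONENTS
  for (i in seq_along(delta_ts)) {
    pair <- .kernel_pair(spec, delta_ts[i], dt)
    u1 <- pair$pre$values
    u2 <- pair$post$values
    du1 <- signal_derivative(pair$pre)$values
    du2 <- signal_derivative(pair$post)$values
    for (k in GDHL_COMPONENTS) {
      out[[k]][i] <- sum(component_product(k, u1, du1, u2, du2)) * dt
    }
  }
  lapply(out, function(dws) kernel_curve(delta_ts, dws))
}

#' Skewed (asymmetric) event waveform
#'
#' A raised-cosine bump whose rise and fall have different durations: the
#' rise occupies `skew` of the support and the fall the rest. Used to
#' demonstrate that the eight component kernels separate once the event is
#' asymmetric.
#'
#' @param spec An [event_spec()].
#' @param skew Fraction of the support taken by the rise, in (0, 1);
#'   0.5 gives the symmetric bump.
#' @param t0,dt,n Grid definition.
#' @return A `gdhl_signal`.
#' @export
skewed_cosine_event <- function(spec, skew = 0.3, t0, dt, n) {
  stopifnot(inherits(spec, "event_spec"), skew > 0, skew < 1)
  t <- t0 + (seq_len(n) - 1) * dt
  onset <- spec$center - spec$half_width
  width <- 2 * spec$half_width
  rise_end <- onset + skew * width
  v <- numeric(length(t))
  up <- t >= onset & t < rise_end
  dn <- t >= rise_end & t <= onset + width
  v[up] <- spec$amplitude * 0.5 *
    (1 - cos(pi * (t[up] - onset) / (skew * width)))
  v[dn] <- spec$amplitude * 0.5 *
    (1 + cos(pi * (t[dn] - rise_end) / ((1 - skew) * width)))
  signal(v, dt = dt, t0 = t0)
}

#' Per-component kernels for an arbitrary event signal
#'
#' Like [component_kernels()] but for any user-supplied waveform (e.g. a
#' [skewed_cosine_event()]): the pre signal is the waveform itself and the
#' post signal is the same waveform delayed by each Delta_t (implemented by
#' an integer-step shift, so delays are rounded to the grid).
#'
#' @param event_signal A `gdhl_signal` holding one event, with enough zero
#'   margin on both sides to absorb the largest delay.
#' @param delta_ts Delay grid.
#' @return Named list of [kernel_curve()]s.
#' @export
component_kernels_signal <- function(event_signal,
                                     delta_ts = seq(-1, 1, by = 0.01)) {
  stopifnot(inherits(event_signal, "gdhl_signal"))
  dt <- event_signal$dt
  u <- event_signal$values
  n <- length(u)
  du <- signal_derivative(event_signal)$values
  shift <- function(x, k) {
    # delay x by k samples, zero-filled
    if (k == 0L) return(x)
    if (k > 0L) c(numeric(k), x[1:(n - k)]) else c(x[(1 - k):n], numeric(-k))
  }
  out <- lapply(GDHL_COMPONENTS, function(k) numeric(length(delta_ts)))
  names(out) <- GDHL_COMPONENTS
  for (i in seq_along(delta_ts)) {
    k_steps <- as.integer(round(delta_ts[i] / dt))
    u2 <- shift(u, k_steps)
    du2 <- shift(du, k_steps)
    for (k in GDHL_COMPONENTS) {
      out[[k]][i] <- sum(component_product(k, u, du, u2, du2)) * dt
    }
  }
  lapply(out, function(dws) kernel_curve(delta_ts, dws))
}

#' Read / write a kernel curve as CSV
#'
#' Dialect: header `delta_t,dw`, `#` comment lines allowed.
#'
#' @param k A [kernel_curve()].
#' @param path File path.
#' @param comment Optional comment line.
#' @return `write_kernel_csv()` returns `path` invisibly;
#'   `read_kernel_csv()` returns a `kernel_curve`.
#' @export
write_kernel_csv <- function(k, path, comment = NULL) {
  stopifnot(inherits(k, "kernel_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# delta_t convention: t_post - t_pre (positive = pre leads)",
             con)
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("delta_t,dw", con)
  writeLines(paste(format(k$delta_ts, digits = 12, trim = TRUE),
                   format(k$dws, digits = 12, trim = TRUE), sep = ","), con)
  invisible(path)
}

#' @rdname write_kernel_csv
#' @export
read_kernel_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("delta_t", "dw") %in% names(d))) {
    stop("kernel CSV needs columns `delta_t` and `dw`", call. = FALSE)
  }
  kernel_curve(d$delta_t, d$dw)
}
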