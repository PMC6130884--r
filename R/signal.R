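#' Uniformly sampled signal
#'
#' Container for a single neuron-related quantity (firing rate, membrane
#' potential, trace, ...) sampled on a uniform time grid. All rule and kernel
#' computations in the package operate on this class.
#'
#' @param values Numeric vector of samples (length >= 2, all finite).
#' @param dt Sampling step, > 0. Time units are the caller's (dimensionless
#'   for the event demos, ms for spike-pair work).
#' @param t0 Time of the first sample.
#'
#' @return An object of class `gdhl_signal`: a list with elements `t0`, `dt`
#'   and `values`.
#' @examples
#' s <- signal(sin(seq(0, 2 * pi, length.out = 100)), dt = 0.01)
#' s
#' @export
signal <- function(values, dt, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("a signal needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("signal values must all be finite", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0)) {
    stop("`t0` must be a single finite number", call. = FALSE)
  }
  structure(list(t0 = as.numeric(t0), dt = as.numeric(dt), values = values),
            class = "gdhl_signal")
}

#' @export
print.gdhl_signal <- function(x, ...) {
  cat(sprintf("<gdhl_signal> %d samples, dt = %g, t in [%g, %g]\n",
              length(x$values), x$dt, x$t0,
              x$t0 + (length(x$values) - 1L) * x$dt))
  cat(sprintf("  range of values: [%g, %g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Sample times of a signal
#'
#' @param s A [signal()].
#' @return Numeric vector `t0 + (0:(n-1)) * dt`.
#' @export
signal_times <- function(s) {
  stopifnot(inherits(s, "gdhl_signal"))
  s$t0 + (seq_along(s$values) - 1) * s$dt
}

.same_grid <- function(a, b, tol = 1e-9) {
  length(a$values) == length(b$values) &&
    abs(a$dt - b$dt) <= tol * max(a$dt, b$dt) &&
    abs(a$t0 - b$t0) <= tol * max(1, abs(a$t0), abs(b$t0))
}

#' Positive and negative part functions
#'
#' `positive_part(x)` is x for x >= 0 and 0 otherwise; `negative_part(x)` is
#' the *magnitude* of the negative side, −x for x <= 0 and 0 otherwise. Both
#' are therefore nonnegative, and `positive_part(x) - negative_part(x) == x`.
#' Applied to a signal derivative they mark the rising and the falling part
#' of an event, the two sub-events the G-DHL rule multiplies.
#'
#' @param x Numeric vector, all finite.
#' @return Nonnegative numeric vector of the same length.
#' @examples
#' positive_part(c(-0.5, 0, 0.7)) # 0 0 0.7
#' negative_part(c(-0.5, 0, 0.7)) # 0.5 0 0
#' @export
positive_part <- function(x) {
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop("`x` must be finite numeric", call. = FALSE)
  }
  pmax(x, 0)
}

#' @rdname positive_part
#' @export
negative_part <- function(x) {
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop("`x` must be finite numeric", call. = FALSE)
  }
  pmax(-x, 0)
}

#' Numerical derivative of a signal
#'
#' Central differences in the interior, one-sided differences at the two
#' boundary samples. The result lives on the same grid.
#'
#' @param s A [signal()] with at least 3 samples.
#' @return A `gdhl_signal` holding du/dt.
#' @export
signal_derivative <- function(s) {
  stopifnot(inherits(s, "gdhl_signal"))
  v <- s$values
  n <- length(v)
  if (n < 3L) stop("derivative needs at least 3 samples", call. = FALSE)
  d <- numeric(n)
  d[1L] <- (v[2L] - v[1L]) / s$dt
  d[n] <- (v[n] - v[n - 1L]) / s$dt
  d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * s$dt)
  signal(d, dt = s$dt, t0 = s$t0)
}

#' Event specification
#'
#' A smooth 'event' — a short monotonic rise followed by a monotonic fall —
#' realised as a raised-cosine bump by [cosine_event()].
#'
#' @param center Time of the event peak.
#' @param half_width Half the event support, > 0.
#' @param amplitude Peak value, > 0.
#' @return An object of class `event_spec`.
#' @export
event_spec <- function(center, half_width, amplitude = 1) {
  if (!is.finite(center)) stop("`center` must be finite", call. = FALSE)
  if (!is.finite(half_width) || half_width <= 0) {
    stop("`half_width` must be > 0", call. = FALSE)
  }
  if (!is.finite(amplitude) || amplitude <= 0) {
    stop("`amplitude` must be > 0", call. = FALSE)
  }
  structure(list(center = center, half_width = half_width,
                 amplitude = amplitude),
            class = "event_spec")
}

#' Raised-cosine event on a uniform grid
#'
#' u(t) = amplitude/2 * (1 + cos(pi (t - center) / half_width)) inside
#' |t - center| <= half_width and 0 outside: one full cosine period over
#' (-pi, pi) scaled and shifted to a nonnegative bump. Both the value and the
#' first derivative vanish at the event edges, so the derivative-part
#' operators see a clean rise and fall.
#'
#' @param spec An [event_spec()].
#' @param t0,dt,n Grid definition: start time, step and number of samples.
#' @return A `gdhl_signal`. If the grid does not cover the event support a
#'   warning is raised and the event is truncated.
#' @export
cosine_event <- function(spec, t0, dt, n) {
  stopifnot(inherits(spec, "event_spec"))
  t <- t0 + (seq_len(n) - 1) * dt
  if (spec$center - spec$half_width < t[1L] - dt / 2 ||
      spec$center + spec$half_width > t[n] + dt / 2) {
    warning("grid does not cover the event support; event truncated",
            call. = FALSE)
  }
  x <- (t - spec$center) / spec$half_width
  v <- ifelse(abs(x) <= 1, spec$amplitude * 0.5 * (1 + cos(pi * x)), 0)
  signal(v, dt = dt, t0 = t0)
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG so seeded generators do not perturb the global stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random mixture of cosine components
#'
#' Average of `n_components` cosines of random frequency (uniform in
#' `freq_range`, cycles per time unit) each rescaled to span (0, 1) over the
#' grid and then multiplied by a random amplitude uniform in (0, 1). The
#' result is a complex but smooth signal in \[0, 1\] carrying many embedded
#' events; it is the standard input for the pre-filtering demonstrations.
#'
#' @param n_components Number of cosines, >= 1.
#' @param freq_range Frequency interval (cycles per unit time).
#' @param t0,dt,n Grid definition.
#' @param seed Integer seed; the same seed always reproduces the same signal.
#' @return A `gdhl_signal` with values in \[0, 1\].
#' @export
random_cosine_mixture <- function(n_components = 4, freq_range = c(0.1, 3),
                                  t0 = 0, dt = 0.001, n = 10001, seed = 1) {
  if (n_components < 1) stop("`n_components` must be >= 1", call. = FALSE)
  stopifnot(length(freq_range) == 2L, freq_range[1L] > 0,
            freq_range[2L] >= freq_range[1L])
  t <- t0 + (seq_len(n) - 1) * dt
  v <- with_seed(seed, {
    acc <- numeric(n)
    for (i in seq_len(n_components)) {
      f <- stats::runif(1, freq_range[1L], freq_range[2L])
      a <- stats::runif(1)
      y <- cos(2 * pi * f * t)
      y <- (y - min(y)) / (max(y) - min(y)) # scaled to (0, 1)
      acc <- acc + a * y
    }
    acc / n_components
  })
  signal(v, dt = dt, t0 = t0)
}

#' Leaky-accumulator eligibility trace
#'
#' Discrete leaky integrator m_t = m_{t-1} + (dt/tau) * (-m_{t-1} + u_{t-1}).
#' The trace outlives its driving event by a time of order `tau`, letting the
#' learning rule relate events separated by a gap.
#'
#' @param s Input [signal()].
#' @param tau Integrator time constant, > 0 (same units as the grid).
#' @param init Trace value at the first sample.
#' @return A `gdhl_signal` on the same grid.
#' @export
leaky_trace <- function(s, tau, init = 0) {
  stopifnot(inherits(s, "gdhl_signal"))
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  u <- s$values
  n <- length(u)
  a <- s$dt / tau
  m <- numeric(n)
  m[1L] <- init
  for (i in 2:n) m[i] <- m[i - 1L] + a * (u[i - 1L] - m[i - 1L])
  signal(m, dt = s$dt, t0 = s$t0)
}

#' Shift a signal to be nonnegative
#'
#' The rule contract requires nonnegative activations. This subtracts
#' `min(s)` when the minimum is negative (leaving the derivative untouched)
#' and returns the signal unchanged otherwise. Nothing is ever clipped.
#'
#' @param s A [signal()].
#' @return A `gdhl_signal` with minimum 0, or `s` unchanged.
#' @export
shift_nonnegative <- function(s) {
  stopifnot(inherits(s, "gdhl_signal"))
  m <- min(s$values)
  if (m >= 0) return(s)
  signal(s$values - m, dt = s$dt, t0 = s$t0)
}

#' Read / write a signal as two-column CSV
#'
#' The dialect is a header line `time,value`, one row per sample, with `#`
#' starting comment lines. The grid must be uniform (checked on read).
#'
#' @param path File path.
#' @return `read_signal_csv()` returns a `gdhl_signal`;
#'   `write_signal_csv()` returns `path` invisibly.
#' @export
read_signal_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time", "value") %in% names(d))) {
    stop("signal CSV needs columns `time` and `value`", call. = FALSE)
  }
  t <- d$time
  if (length(t) < 2L) stop("signal CSV needs at least 2 rows", call. = FALSE)
  steps <- diff(t)
  dt <- stats::median(steps)
  if (any(abs(steps - dt) > 1e-6 * dt)) {
    stop("signal CSV grid is not uniform", call. = FALSE)
  }
  signal(d$value, dt = dt, t0 = t[1L])
}

#' @rdname read_signal_csv
#' @param s Signal to write.
#' @param comment Optional comment line written after the `#` prefix.
#' @export
write_signal_csv <- function(s, path, comment = NULL) {
  stopifnot(inherits(s, "gdhl_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("time,value", con)
  writeLines(paste(format(signal_times(s), digits = 12, trim = TRUE),
                   format(s$values, digits = 12, trim = TRUE), sep = ","),
             con)
  invisible(path)
}
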