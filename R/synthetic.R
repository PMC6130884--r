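#' Specification of a synthetic STDP dataset
#'
#' Ground truth plus sampling scheme for generating STDP point clouds with
#' known provenance — the test bed for the fitting engine.
#'
#' @param coefficients True [gdhl_coefficients()] (the non-zero entries
#'   define the generating subset).
#' @param trace True [trace_params()].
#' @param n_points Number of points, >= 6.
#' @param delta_t_range Interval of inter-spike intervals (ms); must span
#'   both signs.
#' @param sampling `"dense_near_zero"` (half the points uniform in
#'   \[-20, 20\] ms, half over the full range — mimicking experimental
#'   designs that concentrate near coincidence) or `"uniform"`.
#' @param noise_sd Gaussian noise sd as a fraction of the maximum absolute
#'   noiseless Delta_w, >= 0.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(coefficients, trace, n_points = 60,
                           delta_t_range = c(-100, 100),
                           sampling = c("dense_near_zero", "uniform"),
                           noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(coefficients, "gdhl_coefficients"),
            inherits(trace, "trace_params"))
  sampling <- match.arg(sampling)
  if (n_points < 6) stop("`n_points` must be >= 6", call. = FALSE)
  if (delta_t_range[1L] >= 0 || delta_t_range[2L] <= 0) {
    stop("`delta_t_range` must span both signs of delta_t", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(coefficients = coefficients, trace = trace,
                 n_points = as.integer(n_points),
                 delta_t_range = as.numeric(delta_t_range),
                 sampling = sampling, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic STDP dataset
#'
#' Draws inter-spike intervals per the sampling scheme, evaluates the true
#' spike-pair kernel at them, and adds Gaussian noise with sd equal to
#' `noise_sd` times the maximum absolute noiseless Delta_w. The generating
#' spec is attached as attribute `truth`, so the noiseless kernel is
#' recoverable bit-identically from the stored ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @return An [stdp_dataset()] with attribute `truth = spec`.
#' @examples
#' truth <- synthetic_spec(gdhl_coefficients(eta_sp = 0.66, eta_ns = -0.6),
#'                         trace_params(1, 20, 20), seed = 7)
#' d <- generate_stdp(truth)
#' d
#' @export
generate_stdp <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  r <- spec$delta_t_range
  dat <- with_seed(spec$seed, {
    n <- spec$n_points
    if (spec$sampling == "uniform") {
      dt <- stats::runif(n, r[1L], r[2L])
    } else {
      n_near <- n %/% 2L
      near <- stats::runif(n_near, max(r[1L], -20), min(r[2L], 20))
      far <- stats::runif(n - n_near, r[1L], r[2L])
      dt <- c(near, far)
    }
    dt <- sort(dt)
    clean <- spike_kernel_values(spec$coefficients, spec$trace, dt)
    peak <- max(abs(clean))
    if (peak == 0 && spec$noise_sd > 0) {
      stop("zero-amplitude truth cannot carry relative noise", call. = FALSE)
    }
    noise <- if (spec$noise_sd > 0) {
      stats::rnorm(n, 0, spec$noise_sd * peak)
    } else {
      numeric(n)
    }
    list(dt = dt, dw = clean + noise)
  })
  out <- stdp_dataset(dat$dt, dat$dw, label = "synthetic")
  attr(out, "truth") <- spec
  out
}

# Fixture ground truths. Coefficient magnitudes follow published fits of
# the corresponding kernel classes (used purely as plausible generators);
# both trace time constants are 20 ms, a typical STDP window scale.
.fixture_specs <- function() {
  tr <- trace_params(1, 20, 20)
  list(
    causal_like = synthetic_spec(
      gdhl_coefficients(eta_ps = -0.47, eta_ns = 0.66), tr, seed = 101),
    anticausal_like = synthetic_spec(
      gdhl_coefficients(eta_sp = -0.65, eta_ns = 0.61), tr, seed = 102),
    mexican_hat_like = synthetic_spec(
      gdhl_coefficients(sigma_np = -0.52, sigma_pn = -0.48,
                        sigma_nn = 0.77), tr, seed = 103),
    flat_at_zero_like = synthetic_spec(
      gdhl_coefficients(sigma_np = 0.78, sigma_pn = -0.56), tr, seed = 104))
}

#' Named fixture STDP datasets
#'
#' Fixed-seed synthetic datasets shaped like the four qualitative kernel
#' classes seen across STDP experiments: `causal_like` (LTD for negative,
#' LTP for positive intervals), `anticausal_like` (the mirror image),
#' `mexican_hat_like` (LTP centre flanked by LTD lobes) and
#' `flat_at_zero_like` (no plasticity plateau around coincidence).
#'
#' @param name Fixture name.
#' @return An [stdp_dataset()] with attribute `truth`.
#' @export
stdp_fixture <- function(name = c("causal_like", "anticausal_like",
                                  "mexican_hat_like", "flat_at_zero_like")) {
  name <- match.arg(name)
  generate_stdp(.fixture_specs()[[name]])
}

#' Serialise a synthetic ground truth as JSON
#'
#' Sibling metadata for a generated CSV: the generating coefficients,
#' trace parameters, sampling scheme, noise level and seed.
#'
#' @param spec A [synthetic_spec()] (or a dataset's `truth` attribute).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  w <- spec$coefficients$weights
  long <- c(pp = "sigma_pp", pn = "sigma_pn", np = "sigma_np",
            nn = "sigma_nn", sp = "eta_sp", sn = "eta_sn",
            ps = "eta_ps", ns = "eta_ns")
  nz <- w[w != 0]
  names(nz) <- long[names(nz)]
  obj <- list(coefficients = as.list(nz),
              rate = spec$coefficients$rate,
              kappa = spec$trace$kappa,
              tau1 = spec$trace$tau1, tau2 = spec$trace$tau2,
              n_points = spec$n_points,
              delta_t_range = spec$delta_t_range,
              sampling = spec$sampling,
              noise_sd = spec$noise_sd, seed = spec$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
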