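#' STDP dataset
#'
#' Observed spike-timing-dependent plasticity points: inter-spike interval
#' Delta_t (ms, convention t_post - t_pre) versus synaptic change Delta_w
#' (typically percent change; the caller declares the units).
#'
#' @param delta_t Numeric vector of inter-spike intervals (ms).
#' @param dw Numeric vector of synaptic changes, same length.
#' @param label Free-text description.
#' @return An object of class `stdp_dataset` (a data frame with columns
#'   `delta_t` and `dw`).
#' @export
stdp_dataset <- function(delta_t, dw, label = "") {
  delta_t <- as.numeric(delta_t)
  dw <- as.numeric(dw)
  if (length(delta_t) != length(dw)) {
    stop("`delta_t` and `dw` must have equal length", call. = FALSE)
  }
  if (!all(is.finite(delta_t)) || !all(is.finite(dw))) {
    stop("STDP points must be finite", call. = FALSE)
  }
  structure(data.frame(delta_t = delta_t, dw = dw),
            label = label, class = c("stdp_dataset", "data.frame"))
}

#' @export
print.stdp_dataset <- function(x, ...) {
  cat(sprintf("<stdp_dataset> %d points, delta_t in [%g, %g] ms%s\n",
              nrow(x), min(x$delta_t), max(x$delta_t),
              if (nzchar(attr(x, "label"))) paste0(" — ", attr(x, "label"))
              else ""))
  invisible(x)
}

#' Read / write STDP data as CSV
#'
#' Dialect: header `delta_t_ms,dw_percent`, `#` comment lines allowed.
#'
#' @param path File path.
#' @param d An [stdp_dataset()].
#' @param comment Optional comment line.
#' @return `read_stdp_csv()` returns an `stdp_dataset`;
#'   `write_stdp_csv()` returns `path` invisibly.
#' @export
read_stdp_csv <- function(path) {
  d <- tryCatch(utils::read.csv(path, comment.char = "#"),
                error = function(e) {
    stop(sprintf("cannot parse STDP CSV '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (!all(c("delta_t_ms", "dw_percent") %in% names(d))) {
    stop("STDP CSV needs columns `delta_t_ms` and `dw_percent`",
         call. = FALSE)
  }
  bad <- which(!is.finite(d$delta_t_ms) | !is.finite(d$dw_percent))
  if (length(bad)) {
    stop(sprintf("non-numeric STDP data at data row %d of '%s'",
                 bad[1L], path), call. = FALSE)
  }
  stdp_dataset(d$delta_t_ms, d$dw_percent, label = basename(path))
}

#' @rdname read_stdp_csv
#' @export
write_stdp_csv <- function(d, path, comment = NULL) {
  stopifnot(inherits(d, "stdp_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# delta_t convention: t_post - t_pre (positive = pre leads)",
             con)
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("delta_t_ms,dw_percent", con)
  writeLines(paste(format(d$delta_t, digits = 12, trim = TRUE),
                   format(d$dw, digits = 12, trim = TRUE), sep = ","), con)
  invisible(path)
}

#' Fraction of variance unexplained
#'
#' FVU = sum((y - yhat)^2) / sum((y - mean(y))^2): 0 for a perfect fit, 1
#' for a fit no better than the mean. The fit-quality objective minimised
#' by the genetic algorithm.
#'
#' @param observed,predicted Equal-length numeric vectors (>= 2 points;
#'   observed must not be constant).
#' @return Nonnegative number.
#' @export
fvu <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    stop("need equal-length vectors with >= 2 points", call. = FALSE)
  }
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop("observed values have zero variance", call. = FALSE)
  sum((observed - predicted)^2) / tss
}

#' Exponential STDP baseline
#'
#' The standard phenomenological two-branch exponential learning window:
#' a_plus * exp(-Delta_t/tau) for Delta_t > 0 and
#' -a_minus * exp(Delta_t/tau) for Delta_t <= 0.
#'
#' @param delta_t Inter-spike intervals (ms), vectorised.
#' @param tau Decay constant (ms), > 0.
#' @param a_plus,a_minus Branch amplitudes.
#' @return Numeric vector.
#' @export
exp_baseline <- function(delta_t, tau, a_plus = 1, a_minus = 1) {
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  ifelse(delta_t > 0, a_plus * exp(-delta_t / tau),
         -a_minus * exp(delta_t / tau))
}

#' Bayesian information criterion (Gaussian-error form)
#'
#' BIC = n * log(rss / n) + k * log(n), the form obtained from a Gaussian
#' likelihood with the error variance profiled out. Lower is better; the
#' k * log(n) term penalises parameter count.
#'
#' @param n Number of observations, > k.
#' @param rss Residual sum of squares, > 0.
#' @param k Number of free parameters.
#' @return A number.
#' @export
bic_score <- function(n, rss, k) {
  if (n <= k) stop("need n > k", call. = FALSE)
  if (!is.finite(rss) || rss <= 0) stop("need rss > 0", call. = FALSE)
  n * log(rss / n) + k * log(n)
}

#' Genetic-algorithm configuration
#'
#' Settings for the real-coded GA used by [fit_subset()]: tournament
#' selection (size 3), arithmetic crossover, Gaussian mutation, one elite
#' individual, independent restarts. The GA searches the nonlinear trace
#' time constants (tau1, tau2); the rule coefficients are linear in the
#' model and are profiled out by least squares at every evaluation.
#'
#' @param population Individuals per generation, >= 10.
#' @param generations Generations per restart, >= 1.
#' @param mutation_scale Gaussian mutation sd as a fraction of each
#'   parameter range.
#' @param crossover_rate Probability of crossover per offspring.
#' @param restarts Independent GA runs; the best individual overall wins.
#' @param seed Integer seed; all fitting randomness derives from it.
#' @param bounds Named list with elements `sigma`, `eta` (coefficient
#'   boxes) and `tau` (time-constant box, ms).
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population = 100, generations = 200,
                      mutation_scale = 0.1, crossover_rate = 0.7,
                      restarts = 5, seed = 1,
                      bounds = list(sigma = c(-5, 5), eta = c(-5, 5),
                                    tau = c(1, 100))) {
  if (population < 10) stop("`population` must be >= 10", call. = FALSE)
  if (generations < 1) stop("`generations` must be >= 1", call. = FALSE)
  stopifnot(is.list(bounds), all(c("sigma", "eta", "tau") %in% names(bounds)))
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 mutation_scale = mutation_scale,
                 crossover_rate = crossover_rate,
                 restarts = as.integer(restarts),
                 seed = as.integer(seed), bounds = bounds),
            class = "ga_config")
}

.sigma_components <- c("pp", "pn", "np", "nn")

# Fast design-matrix builder for the GA inner loop: closed-form component
# kernels without per-call validation (columns in `subset` order).
.spike_cols <- function(subset, delta_t, tau1, tau2) {
  lambda <- 1 / tau1 + 1 / tau2
  cc <- delta_t / tau2
  f1s <- lapply(c(s = "s", p = "p", n = "n"), .spike_factor,
                kappa = 1, tau = tau1)
  f2s <- lapply(c(s = "s", p = "p", n = "n"), .spike_factor,
                kappa = 1, tau = tau2)
  X <- matrix(0, length(delta_t), length(subset))
  for (j in seq_along(subset)) {
    f1 <- f1s[[substr(subset[j], 1L, 1L)]]
    f2 <- f2s[[substr(subset[j], 2L, 2L)]]
    L <- pmax(f1$a, delta_t + f2$a)
    U <- pmin(f1$b, delta_t + f2$b)
    r0 <- f2$p0 - f2$p1 * delta_t
    q0 <- f1$p0 * r0
    q1 <- f1$p0 * f2$p1 + f1$p1 * r0
    q2 <- f1$p1 * f2$p1
    X[, j] <- .poly_exp_integral(q0, q1, rep(q2, length(delta_t)),
                                 cc, lambda, L, U)
  }
  X
}

# Profiled objective: given (tau1, tau2), the kernel is linear in the
# subset coefficients, so solve them by least squares, project onto the
# coefficient box and score the FVU.
.profiled_fit <- function(tau1, tau2, subset, delta_t, dw, bounds) {
  X <- .spike_cols(subset, delta_t, tau1, tau2)
  ls <- tryCatch(.lm.fit(X, dw), error = function(e) NULL)
  b <- numeric(ncol(X))
  if (!is.null(ls)) {
    bb <- ls$coefficients
    bb[is.na(bb)] <- 0
    b[ls$pivot] <- bb  # undo column pivoting
  }
  lim <- ifelse(subset %in% .sigma_components,
                bounds$sigma[2L], bounds$eta[2L])
  lo <- ifelse(subset %in% .sigma_components,
               bounds$sigma[1L], bounds$eta[1L])
  b <- pmin(pmax(b, lo), lim)
  pred <- as.numeric(X %*% b)
  list(coef = b, fvu = fvu(dw, pred))
}

# One real-coded GA run over (tau1, tau2); RNG state is the caller's.
# `init` rows are injected into the initial population (deterministic
# multistart seeds; elitism keeps the best of them alive).
.ga_run <- function(objective, lo, hi, config, init = NULL) {
  npar <- length(lo)
  pop <- matrix(stats::runif(config$population * npar, lo, hi),
                ncol = npar, byrow = TRUE)
  if (!is.null(init)) {
    keep <- min(nrow(init), nrow(pop))
    pop[seq_len(keep), ] <- init[seq_len(keep), , drop = FALSE]
  }
  fit <- apply(pop, 1L, objective)
  for (g in seq_len(config$generations)) {
    newpop <- matrix(0, config$population, npar)
    best <- which.min(fit)
    newpop[1L, ] <- pop[best, ]  # elitism
    for (i in 2:config$population) {
      pick <- function() {
        cand <- sample.int(config$population, 3L)
        cand[which.min(fit[cand])]
      }
      p1 <- pop[pick(), ]
      if (stats::runif(1) < config$crossover_rate) {
        p2 <- pop[pick(), ]
        u <- stats::runif(npar)
        child <- u * p1 + (1 - u) * p2
      } else {
        child <- p1
      }
      mut <- stats::runif(npar) < 0.5
      child[mut] <- child[mut] +
        stats::rnorm(sum(mut), 0, config$mutation_scale * (hi - lo)[mut])
      newpop[i, ] <- pmin(pmax(child, lo), hi)
    }
    pop <- newpop
    fit <- apply(pop, 1L, objective)
  }
  best <- which.min(fit)
  list(par = pop[best, ], value = fit[best])
}

#' Fit one component subset to an STDP dataset
#'
#' Minimises the FVU of the spike-pair kernel built from the given
#' components over the trace time constants (tau1, tau2) with a seeded
#' real-coded genetic algorithm; at each candidate (tau1, tau2) the subset
#' coefficients are solved by least squares (the kernel is linear in them)
#' and projected onto the configured box. The trace amplitude kappa is
#' fixed at 1: every component scales as kappa^2, so kappa is exactly
#' degenerate with the coefficient scale and fixing it makes the
#' coefficients identifiable.
#'
#' @param dataset An [stdp_dataset()] with more points than parameters
#'   (|subset| + 2) and at least 6.
#' @param subset Character vector of component ids, length >= 1.
#' @param config A [ga_config()].
#' @return List with `subset`, `coefficients` (a [gdhl_coefficients()]
#'   with non-subset entries 0), `trace` (a [trace_params()], kappa = 1),
#'   and `fvu`. Deterministic given `config$seed`.
#' @export
fit_subset <- function(dataset, subset, config = ga_config()) {
  stopifnot(inherits(dataset, "stdp_dataset"), inherits(config, "ga_config"))
  subset <- as.character(subset)
  if (length(subset) < 1L || !all(subset %in% GDHL_COMPONENTS)) {
    stop("`subset` must name at least one valid component", call. = FALSE)
  }
  n <- nrow(dataset)
  k <- length(subset) + 2L
  if (n < 6L || n <= k) {
    stop("dataset too small relative to parameter count", call. = FALSE)
  }
  bounds <- config$bounds
  objective <- function(x) {
    .profiled_fit(x[1L], x[2L], subset, dataset$delta_t, dataset$dw,
                  bounds)$fvu
  }
  lo <- rep(bounds$tau[1L], 2L)
  hi <- rep(bounds$tau[2L], 2L)
  # deterministic coarse scan of the (tau1, tau2) plane; its best point is
  # injected into every GA restart so smooth basins are never missed
  tau_grid <- c(2, 5, 10, 20, 40, 80)
  tau_grid <- tau_grid[tau_grid >= bounds$tau[1L] & tau_grid <= bounds$tau[2L]]
  grid <- as.matrix(expand.grid(tau1 = tau_grid, tau2 = tau_grid))
  gval <- apply(grid, 1L, objective)
  seed_pt <- grid[which.min(gval), , drop = FALSE]
  best <- with_seed(config$seed, {
    runs <- lapply(seq_len(config$restarts), function(r) {
      .ga_run(objective, lo, hi, config, init = seed_pt)
    })
    runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  })
  # deterministic local polish of the GA optimum (box enforced by clamping)
  polish <- stats::optim(best$par,
                         function(x) objective(pmin(pmax(x, lo), hi)),
                         method = "Nelder-Mead",
                         control = list(maxit = 50, reltol = 1e-8))
  par <- pmin(pmax(polish$par, lo), hi)
  if (polish$value > best$value) par <- best$par
  sol <- .profiled_fit(par[1L], par[2L], subset,
                       dataset$delta_t, dataset$dw, bounds)
  w <- stats::setNames(rep(0, 8L), GDHL_COMPONENTS)
  w[subset] <- sol$coef
  coefficients <- gdhl_coefficients(w[["pp"]], w[["pn"]], w[["np"]],
                                    w[["nn"]], w[["sp"]], w[["sn"]],
                                    w[["ps"]], w[["ns"]])
  list(subset = sort(subset),
       coefficients = coefficients,
       trace = trace_params(1, par[1L], par[2L]),
       fvu = sol$fvu)
}

#' Automatic component-subset selection for an STDP dataset
#'
#' Enumerates every non-empty subset of the eight rule components (up to
#' `max_components`, 255 models at the maximum), fits each independently
#' with [fit_subset()], scores each with [bic_score()] using
#' k = |subset| + 2 free parameters (coefficients plus tau1, tau2), and
#' returns the minimum-BIC model together with the full BIC table. Ties
#' are broken in favour of fewer components, then lexicographic subset
#' order.
#'
#' @param dataset An [stdp_dataset()].
#' @param config A [ga_config()]; subset fits use seeds derived from
#'   `config$seed` so the whole selection is reproducible.
#' @param max_components Largest subset size to consider (default 8).
#' @return An object of class `gdhl_fit`: list with `subset`,
#'   `coefficients`, `trace`, `fvu`, `bic`, `n_params`, `bic_table`
#'   (a data frame over all fitted subsets) and `seed`.
#' @export
model_select <- function(dataset, config = ga_config(), max_components = 8) {
  stopifnot(inherits(dataset, "stdp_dataset"), inherits(config, "ga_config"))
  n <- nrow(dataset)
  subsets <- list()
  for (m in seq_len(max_components)) {
    subsets <- c(subsets,
                 utils::combn(GDHL_COMPONENTS, m, simplify = FALSE))
  }
  tss <- sum((dataset$dw - mean(dataset$dw))^2)
  fits <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  for (j in seq_along(subsets)) {
    sub <- subsets[[j]]
    cfg <- config
    cfg$seed <- config$seed + j  # per-subset stream, reproducible
    fits[[j]] <- fit_subset(dataset, sub, cfg)
    # relative floor at the optimiser's convergence tolerance: residual
    # differences below it are numerical noise and must not drive the BIC
    # (the size tie-break then favours the sparser model)
    rss <- max(fits[[j]]$fvu * tss, 1e-8 * tss)
    rows[[j]] <- data.frame(
      subset = paste(sort(sub), collapse = "+"),
      size = length(sub),
      tau1 = fits[[j]]$trace$tau1,
      tau2 = fits[[j]]$trace$tau2,
      fvu = fits[[j]]$fvu,
      bic = bic_score(n, rss, length(sub) + 2L))
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$bic, tab$size, tab$subset)
  win <- ord[1L]
  fit <- fits[[win]]
  structure(list(subset = fit$subset,
                 coefficients = fit$coefficients,
                 trace = fit$trace,
                 fvu = fit$fvu,
                 bic = tab$bic[win],
                 n_params = length(fit$subset) + 2L,
                 bic_table = tab[order(tab$bic), , drop = FALSE],
                 seed = config$seed),
            class = "gdhl_fit")
}

#' @export
print.gdhl_fit <- function(x, ...) {
  cat("<gdhl_fit>\n")
  cat(sprintf("  selected components: {%s}\n",
              paste(x$subset, collapse = ", ")))
  w <- x$coefficients$weights
  cat(sprintf("  coefficients: %s\n",
              paste(sprintf("%s=%.4g", x$subset, w[x$subset]),
                    collapse = ", ")))
  cat(sprintf("  tau1 = %.3g ms, tau2 = %.3g ms (kappa fixed at 1)\n",
              x$trace$tau1, x$trace$tau2))
  cat(sprintf("  FVU = %.4g, BIC = %.4g (%d parameters)\n",
              x$fvu, x$bic, x$n_params))
  invisible(x)
}

#' Predict synaptic change from a fitted model
#'
#' @param object A `gdhl_fit` from [model_select()] (or a list with
#'   `coefficients` and `trace` as from [fit_subset()]).
#' @param delta_t Inter-spike intervals (ms).
#' @param ... Unused.
#' @return Numeric vector of predicted Delta_w.
#' @export
predict.gdhl_fit <- function(object, delta_t, ...) {
  spike_kernel_values(object$coefficients, object$trace, delta_t)
}

#' Write a fit result as JSON
#'
#' Records the selected subset, its coefficients, the trace time constants,
#' FVU, BIC, the seed and the full BIC table, so the fit can be audited and
#' re-evaluated.
#'
#' @param fit A `gdhl_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "gdhl_fit"))
  w <- fit$coefficients$weights
  obj <- list(subset = fit$subset,
              coefficients = as.list(w[fit$subset]),
              tau1 = fit$trace$tau1, tau2 = fit$trace$tau2, kappa = 1,
              fvu = fit$fvu, bic = fit$bic, n_params = fit$n_params,
              seed = fit$seed,
              bic_table = fit$bic_table)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
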