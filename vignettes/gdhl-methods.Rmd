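---
title: "Differential Hebbian learning with gdhl: models, kernels and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential Hebbian learning with gdhl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdhl)
```

## The model

Hebbian rules strengthen a synapse when pre- and post-synaptic activity
*co-occur*; differential Hebbian learning (DHL) rules instead respond to the
*temporal relation* between activity changes, read off the signal
derivatives. An *event* is a short stretch of signal that rises
monotonically and then falls; the positive part of the derivative,
$[\dot u]^+ = \max(\dot u, 0)$, marks the rising (starting) portion of an
event and the negative-part magnitude $[\dot u]^- = \max(-\dot u, 0)$ its
falling (ending) portion.

The general rule implemented here combines, by multiplication, the three
pre-synaptic elements $\{u_1, [\dot u_1]^+, [\dot u_1]^-\}$ with the three
post-synaptic elements $\{u_2, [\dot u_2]^+, [\dot u_2]^-\}$, excluding the
signal-by-signal product (it reproduces the plain Hebb rule, which the
`pp` + `nn` pair already covers):

$$
\dot w = \sigma_{pp}[\dot u_1]^+[\dot u_2]^+ + \sigma_{pn}[\dot u_1]^+[\dot u_2]^-
       + \sigma_{np}[\dot u_1]^-[\dot u_2]^+ + \sigma_{nn}[\dot u_1]^-[\dot u_2]^-
$$
$$
\qquad + \eta_{sp}\,u_1[\dot u_2]^+ + \eta_{sn}\,u_1[\dot u_2]^-
       + \eta_{ps}[\dot u_1]^+u_2 + \eta_{ns}[\dot u_1]^-u_2 .
$$

The eight products are the rule *components*, named by two letters
(pre factor, post factor; `s` = signal, `p` = positive derivative part,
`n` = negative derivative part). The signed coefficients decide whether a
component potentiates or depresses the synapse and how strongly; classic
rules are coefficient patterns (`gdhl_preset()`): Kosko's
$\dot u_1 \dot u_2$ is $\sigma = (1, -1, -1, 1)$, the Porr–Wörgötter rule
$u_1 \dot u_2$ is $\eta_{sp} = \lambda, \eta_{sn} = -\lambda$, and the
symmetric Hebb rule is $\sigma_{pp} = \sigma_{nn} = 1$.

Design choices worth making explicit:

* **The rate multiplier.** The classic formulations carry a $1/\tau$
  factor. Here it is a single `rate` multiplier applied after the sum
  (default 1): it keeps the rule linear in its whole parameter vector, and
  any per-component scale is absorbed by the coefficients themselves.
* **Nonnegativity is a contract, not a silent fix.** The rule assumes
  nonnegative activations. `gdhl_update()` rejects negative activations
  rather than clipping them; `shift_nonnegative()` is the explicit
  pre-processing step (it subtracts the minimum, which leaves every
  derivative unchanged).
* **Integration.** `gdhl_integrate()` accumulates $\dot w\,\Delta t$ by
  explicit Euler. The integrand is bounded and non-stiff, so the Riemann
  reading of the kernel integral is adequate; kernel values change by less
  than $10^{-3}$ relative under a 2$\times$ step refinement (tested).
* **Derivatives.** Central differences in the interior, one-sided at the
  boundaries: second-order accurate, and symmetric events yield symmetric
  kernels to machine precision.

## Learning kernels for event waveforms

The *learning kernel* $\Delta w(\Delta t)$ is the total weight change when
the post-synaptic event lags the pre-synaptic one by $\Delta t$ (sign
convention everywhere: $\Delta t = t_{post} - t_{pre}$, positive when the
pre event leads). `numerical_kernel()` builds the two signals per delay and
integrates the rule; the window is the union of the two event supports
padded by one full event width, where the integrand is identically zero, so
the infinite-limit integral is computed exactly.

The demonstration event is a raised-cosine bump,
$u(t) = \tfrac{A}{2}(1 + \cos(\pi (t - c)/h))$ on $|t - c| \le h$: a single
cosine period scaled and shifted to a nonnegative bump. Its value *and*
slope vanish at the edges, which makes it a clean "event" for the
derivative-part operators. Any affine variant of this choice only rescales
kernels.

With symmetric events the `ps`/`sn` component kernels coincide exactly, as
do `sp`/`ns` (time reversal maps one onto the other); an asymmetric event —
`skewed_cosine_event()` gives the rise and fall different durations —
separates all eight kernels. Both facts are verified in the test suite.

## Spike pairs: closed-form kernels under alpha traces

For STDP experiments the events are spikes. A spike is modelled as a Dirac
impulse, so its eligibility trace is just the alpha function shifted to the
spike time: $\varepsilon(t) = \kappa (t/\tau)\,e^{1 - t/\tau}$ for
$t \ge 0$, normalised to peak at $\kappa$ when $t = \tau$ (any other common
normalisation differs by a constant that the fitted coefficients absorb).
The trace derivative is positive on $(0, \tau)$ and negative on
$(\tau, \infty)$ — these lobes, plus the trace itself, are the `p`, `n`
and `s` factors of the spike-pair components.

Each component kernel is a definite integral of the product of one pre
factor (spike at 0, constant $\tau_1$) and one post factor (spike at
$\Delta t$, constant $\tau_2$), over the overlap of their supports — an
interval with endpoints drawn from $\{0, \tau_1, \Delta t,
\Delta t + \tau_2, \infty\}$, which makes every kernel piecewise in
$\Delta t$. The key simplification exploited by `spike_component_dw()` is
that after expanding the product, the integrand is always

$$ q(t)\, e^{\Delta t/\tau_2}\, e^{-\lambda t}, \qquad
   \lambda = 1/\tau_1 + 1/\tau_2, $$

with $q$ a quadratic polynomial: a single exponential rate appears, so the
antiderivative is evaluated exactly for *all* $\tau_1, \tau_2$ — including
$\tau_1 = \tau_2$, which therefore needs no special branch and suffers no
cancellation (formulations that keep the two exponentials separate develop
$(\tau_1 - \tau_2)$ denominators; this one cannot). The exponent is
non-positive over every integration domain, so no overflow is possible
either. An independent adaptive-quadrature route
(`method = "quadrature"`) guards the closed forms: the test suite and the
acceptance script sweep all 8 components over three $\tau$ regimes
($\tau_1 = 1.5\tau_2$, $\tau_1 = \tau_2$, $\tau_1 = 0.75\tau_2$) and 41
delays and require $10^{-8}$ relative agreement.

Structural properties, all tested: `pp` peaks exactly at $\Delta t = 0$;
with $\tau_1 = \tau_2$, `np` is identically zero for $\Delta t \le 0$ and
`pn` for $\Delta t \ge 0$ (their factor supports cannot overlap); `nn`
peaks at positive delays when $\tau_1 > \tau_2$ and negative when
$\tau_1 < \tau_2$; every unit-coefficient kernel is nonnegative and scales
as $\kappa^2$. `spike_kernel_peak()` locates maxima by a grid scan plus
golden-section refinement and reports the method used.

```{r spike-kernel-example}
p <- trace_params(kappa = 1, tau1 = 20, tau2 = 20)
spike_kernel(gdhl_coefficients(eta_sp = 0.66, eta_ns = -0.60), p,
             seq(-80, 80, by = 20))
```

## Traces and pre-filters for arbitrary signals

Two mechanisms connect the rule to realistic signals:

* **Leaky traces.** `leaky_trace()` implements the discrete leaky
  accumulator $m_t = m_{t-1} + (\Delta t/\tau)(-m_{t-1} + u_{t-1})$. Events
  separated by a silent gap produce *exactly* zero weight change (every
  product term vanishes); their traces overlap and restore the
  interaction. `gap_trace_demo()` packages this contrast.
* **Pre-filters.** `simulate_filtered_pair()` feeds two random
  cosine-mixture signals through rise ($[\dot u]^+$) or fall
  ($[\dot u]^-$) detectors before the rule: the filter choice decides
  *which* signal changes count as events, and thereby what the rule
  learns. The mixture generator follows the standard recipe — four
  cosines, frequencies uniform in $[0.1, 3]$ cycles per time unit, each
  rescaled to $(0,1)$ and given a uniform random amplitude. The default
  window is 10 time units, chosen so each signal carries many events
  (one to thirty cycles per component), which is the premise of the
  demonstration.

One limitation found while characterising this demonstration deserves
record. For *independently generated* signal pairs the population mean
drift of the filtered Porr–Wörgötter weight is statistically
indistinguishable from zero under either filter choice (the drift of any
single pair can be large; its sign is pair-specific). Within one pair the
two filterings do drift oppositely more often than chance (about two-thirds
of seeds), and a strong, reliable sign reversal appears only when the
window is short enough to hold roughly one event per signal — a regime that
contradicts the multi-event premise, so the default window was not chosen
that way. Conclusions about systematic drift direction should therefore be
drawn per signal pair, not across pairs.

## Fitting STDP datasets

An STDP dataset is a set of points $(\Delta t_i, \Delta w_i)$. The fitting
engine asks: which components, with what coefficients and trace constants,
explain it best without overfitting?

* **Objective.** Fraction of variance unexplained,
  $\mathrm{FVU} = \mathrm{RSS}/\mathrm{TSS}$ — scale-free in the
  $\Delta w$ units.
* **Identifiability.** Every component scales as $\kappa^2$, so the trace
  amplitude is exactly degenerate with the coefficient scale; $\kappa$ is
  fixed at 1 during fitting and the coefficients carry the scale.
* **Search.** For a given subset the kernel is *linear* in its
  coefficients, so at each candidate $(\tau_1, \tau_2)$ they are solved by
  ordinary least squares (projected onto the $[-5, 5]$ coefficient box) and
  only the two time constants are searched by a real-coded genetic
  algorithm (tournament selection of size 3, arithmetic crossover,
  Gaussian mutation at 0.1 of the parameter range, one elite, independent
  restarts; $\tau \in [1, 100]$ ms). Each restart's initial population is
  seeded with the best point of a deterministic coarse $\tau$-grid scan,
  and the final GA optimum gets a deterministic Nelder–Mead polish, so
  smooth basins are never missed at small budgets. Profiling the linear part keeps every subset's fit
  near its global optimum at a small evaluation budget, which matters
  because model comparison is only fair between well-optimised models.
  All randomness flows from the `ga_config()` seed; identical seeds give
  identical fits.
* **Selection.** `model_select()` fits all 255 non-empty component subsets
  and scores each with the Gaussian-profile BIC,
  $n \ln(\mathrm{RSS}/n) + k \ln n$, $k = |\text{subset}| + 2$ (the
  coefficients plus the two time constants). Ties break toward fewer
  components, then lexicographic order. The two-branch exponential window
  (`exp_baseline()`) is available as the conventional phenomenological
  baseline.

The default `ga_config()` budget (population 100, 200 generations, 5
restarts) is sized for a careful standalone fit. The tests and the
acceptance script use a reduced budget (population 12, 8 generations, 1
restart, plus the polish), which the profiled objective makes sufficient:
the problem sizes there are 60-point datasets and the full 255-subset
enumeration.

## Synthetic data: what it does and does not emulate

`generate_stdp()` draws delays either uniformly or with half the points
concentrated in $[-20, 20]$ ms (`dense_near_zero`, the default — real STDP
designs oversample near coincidence), evaluates the true kernel, and adds
Gaussian noise with standard deviation expressed as a fraction of the peak
absolute kernel value (default 5%). It stores its ground truth for
bit-exact auditing. The named fixtures reproduce the four qualitative
kernel classes seen across experiments (causal, anticausal, Mexican-hat,
flat-at-zero), with coefficient magnitudes borrowed from published fits of
those classes purely as generators.

What passing recovery tests on these data shows: the engine can identify a
sparse generating component set and its parameters from realistically
sized, realistically noisy point clouds. What it does not show: robustness
to experimental artefacts absent from the generator — pairing-frequency
effects, outliers, heteroscedastic noise, digitisation error — nor anything
about datasets whose true generating process is not a spike-pair kernel.

A structural caveat for recovery experiments with equal trace constants:
when $\tau_1 = \tau_2$ the spike-pair kernels obey exact mirror identities
$K_{sp}(\Delta t) = K_{ps}(-\Delta t)$ and
$K_{ns}(\Delta t) = K_{sn}(-\Delta t)$, so the mirrored subset spans
near-identical fits of an asymmetric kernel. At a few percent noise the
mirror twin (or a near-degenerate three-component set) can attain a
genuinely lower residual on a substantial minority of noise draws, in which
case BIC — correctly — selects it. Exact-subset recovery rates around
70–80% under such conditions reflect the data's information content, not an
optimiser failure; published fits of similar datasets show the same
component ambiguity.

## Numerical choices and degenerate inputs

* Equal-grid checks compare `t0` and `dt` at $10^{-9}$ relative tolerance.
* `.lm.fit` handles rank-deficient design matrices (collinear component
  columns); dropped coefficients become exactly 0.
* Before the BIC logarithm the RSS is floored at $10^{-8}$ of the total
  sum of squares — the optimiser's own convergence tolerance. On noiseless
  data every adequate model reaches this floor, residual differences below
  it are numerical noise, and the size tie-break then correctly selects
  the sparsest adequate model.
* Quadrature for the oracle splits the integration at the trace peak
  times, where the integrand has kinks, and truncates infinite tails only
  where the integrand is below $10^{-280}$ of its scale.
* Generated randomness never perturbs the caller's RNG stream: all seeded
  generators save and restore `.Random.seed`.

## Limitations

Spike triplets and quadruplets, higher-order-derivative rules, weight
bounds or decay terms, and bandpass/resonator pre-filter banks beyond the
leaky integrator are out of scope. The CLI reads JSON (or YAML)
configurations; fits are single-threaded.
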