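# gdhl — general differential Hebbian learning and STDP kernel fitting

Hebbian plasticity rules respond to the *co-occurrence* of pre- and
post-synaptic activity; differential Hebbian learning (DHL) rules respond
to the *temporal order* of activity changes, which they read off the
positive and negative parts of the signal derivatives. `gdhl` implements a
general DHL rule that linearly combines the eight products of the
pre-synaptic elements {u₁, [u̇₁]⁺, [u̇₁]⁻} with the post-synaptic elements
{u₂, [u̇₂]⁺, [u̇₂]⁻} (the signal×signal product excluded):

    ẇ = σ_pp [u̇₁]⁺[u̇₂]⁺ + σ_pn [u̇₁]⁺[u̇₂]⁻ + σ_np [u̇₁]⁻[u̇₂]⁺ + σ_nn [u̇₁]⁻[u̇₂]⁻
      + η_sp u₁[u̇₂]⁺ + η_sn u₁[u̇₂]⁻ + η_ps [u̇₁]⁺u₂ + η_ns [u̇₁]⁻u₂

Classic rules are coefficient presets: Kosko's u̇₁·u̇₂, the Porr–Wörgötter
rule u₁·u̇₂, the symmetric Hebb rule, and the causal / anticausal /
coincidence / flat-at-zero demonstration rules.

The package is for computational neuroscientists and neural-network
modellers who want to

* integrate the rule step by step over arbitrary sampled signals
  (`gdhl_integrate()`), with leaky-trace and derivative-part pre-filters
  (`leaky_trace()`, `simulate_filtered_pair()`);
* compute learning kernels Δw(Δt) numerically for any event waveform
  (`numerical_kernel()`, `component_kernels()`);
* evaluate spike-pair kernels in closed form for Dirac spikes with
  α-function eligibility traces (`spike_component_dw()`, `spike_kernel()`),
  guarded by an independent quadrature oracle;
* fit spike-timing-dependent-plasticity (STDP) datasets automatically:
  exhaustive component-subset enumeration, a seeded real-coded genetic
  algorithm with the linear coefficients profiled out by least squares,
  and Bayesian-information-criterion model selection (`model_select()`);
* generate synthetic STDP datasets with known ground truth
  (`generate_stdp()`, `stdp_fixture()`).

Sign convention everywhere: Δt = t_post − t_pre, so positive delays mean
the pre-synaptic event leads.

## Worked example

A causal STDP kernel built from two mixed components (η_sp = 0.66,
η_ns = −0.60) with equal 20 ms trace constants, then recovered from noisy
synthetic data:

```r
library(gdhl)

p <- trace_params(kappa = 1, tau1 = 20, tau2 = 20)
spike_kernel(gdhl_coefficients(eta_sp = 0.66, eta_ns = -0.60), p,
             seq(-80, 80, by = 20))
#> <kernel_curve> 9 delays in [-80, 80]; extreme dw = 0.222875 at dt = 20

truth <- synthetic_spec(gdhl_coefficients(eta_sp = 0.66, eta_ns = -0.60),
                        trace_params(1, 20, 20), n_points = 60,
                        noise_sd = 0.05, seed = 1)
d <- generate_stdp(truth)
d
#> <stdp_dataset> 60 points, delta_t in [-95.3338, 72.2419] ms — synthetic

fit <- fit_subset(d, c("sp", "ns"),
                  ga_config(population = 12, generations = 8,
                            restarts = 1, seed = 2))
```

The fit reports `fvu 0.0045`, coefficients `eta_sp 0.650` and
`eta_ns -0.572`, and time constants `tau1 19.4`, `tau2 20.0` ms: the
generating parameters are recovered within a few percent from 60 points at
5% noise, and the fraction of variance unexplained (FVU, residual over
total sum of squares) shows the kernel explains ~99.5% of the variance.
Component kernels have interpretable shapes — for example the `pp`
(rise×rise) kernel always peaks at coincidence:

```r
spike_kernel_peak("pp", p)
#> pp peak at delta_t = 3.64e-15, dw = 0.0799
```

`model_select()` extends this to the full engine: it fits all 255
component subsets, scores each with BIC = n·ln(RSS/n) + k·ln(n)
(k = subset size + 2), and returns the sparsest adequate model with its
complete BIC table.

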