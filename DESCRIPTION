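Package: gdhl
Title: General Differential Hebbian Learning and STDP Kernel Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the general differential Hebbian learning (G-DHL)
    rule: step-by-step synaptic weight updates driven by the positive and
    negative parts of pre- and post-synaptic signal derivatives, numerical
    learning kernels for arbitrary event waveforms, closed-form spike-pair
    kernels under alpha-function eligibility traces, and an automatic
    model-comparison engine (exhaustive component-subset enumeration, genetic
    algorithm parameter search, BIC selection) for fitting spike-timing
    dependent plasticity (STDP) datasets. Includes a synthetic STDP data
    generator with known ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
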