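Package: mfneuron
Title: Stochastic Mean-Field Neural Networks and Propagation-of-Chaos Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-population networks of stochastic FitzHugh-Nagumo and
    Hodgkin-Huxley neurons with Langevin channel/synapse noise and random maximal
    synaptic conductances (white-noise or sign-preserving Cox-Ingersoll-Ross
    dynamics), solves the associated McKean-Vlasov mean-field limits by a
    Monte-Carlo Picard fixed-point iteration, and measures the propagation-of-chaos
    error empirically through a pathwise coupling between the finite network and
    independent mean-field copies driven by the same Brownian increments. Includes
    numerical verification of the structural hypotheses (compactly supported noise
    envelope, coercive gating rates, one-sided Lipschitz membrane drift) and of the
    rectangular-cylinder invariance of gating and synaptic variables in [0,1].
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
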