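---
title: "Stochastic mean-field neural networks: models, numerics, and chaos diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic mean-field neural networks: models, numerics, and chaos diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfneuron)
```

## The models

`mfneuron` simulates networks of `N` neurons split over `p` populations with
fixed proportions `c_gamma = N_gamma / N`. Each neuron `i` of population
`alpha` carries a membrane potential `V_i` (mV), a synaptic variable
`y_i` (the proportion of available neurotransmitter, constrained to [0, 1]),
and either a recovery variable `w_i` (FitzHugh-Nagumo) or gating proportions
`n_i, m_i, h_i` (Hodgkin-Huxley). Time is in ms, rates in 1/ms.

The membrane equation couples an intrinsic drift `F_alpha` with chemical
synaptic input. A presynaptic neuron `j` of population `gamma` contributes a
current `-g_ij (V_i - Vrev_{alpha gamma})`, where the conductance `g_ij` is
the product of a maximal conductance and `y_j`. Averaging over the
presynaptic population makes the interaction a function of the empirical mean
of `y` alone; two models describe the maximal conductance:

* **simple** - the conductance fluctuates around its mean `Jbar` as white
  noise with intensity `sigma_J`; the interaction then contributes a drift
  term scaled by `Jbar` and a diffusion term scaled by `sigma_J`, both
  multiplied by the empirical mean of `y`. This model does not guarantee
  positive conductances.
* **sign-preserving** - each neuron owns one Cox-Ingersoll-Ross (CIR)
  process per target population,
  `dJ = theta (Jbar - J) dt + sigma_J sqrt(J) dB`, which stays non-negative.
  This is the package's reference model.

Synaptic and gating variables follow Langevin (diffusion) approximations of
the underlying jump dynamics of finitely many channels: for a generic
proportion `x` with opening rate `rho(V)` and closing rate `zeta(V)`,

```
dx = (rho(V)(1 - x) - zeta(V) x) dt + sqrt(|rho(V)(1 - x) + zeta(V) x|) chi(x) dW.
```

The envelope `chi` is bounded, Lipschitz, and compactly supported inside
(0, 1). That support condition is what keeps the proportions in [0, 1]: the
diffusion vanishes at and beyond the boundary while the drift points inward
(`rho > 0` at `x = 0`, `-zeta < 0` at `x = 1`). `check_boundary_conditions()`
verifies both clauses on grids that extend beyond [0, 1], and
`run_gate_excursions()` realizes the statement empirically; replacing `chi`
with a constant envelope (`chi_fun("constant")`) is the shipped negative
control, which produces excursions with positive frequency.

The synaptic variable has the same structure with `rho = a_r S(V)` and
`zeta = a_d`, where `S(v) = C / (1 + exp(-lambda (v - delta)))` is the
sigmoidal release function.

## The mean-field limit and its Picard solution

As the population sizes grow at fixed proportions, the empirical means of
`y` concentrate and each neuron decouples: the limit process of population
`alpha` solves the same SDE with `E[y_t^gamma]` in place of the empirical
mean (a McKean-Vlasov equation - the coefficients depend on the law of the
solution). Two path functionals close the system: the mean release path
`sbar_alpha(t) = E[S_alpha(V_t^alpha)]` and the mean synaptic path
`ybar_alpha(t) = E[y_t^alpha]`. Because the synaptic diffusion averages
out, `ybar` solves the linear equation

```
dybar/dt = a_r sbar(t) (1 - ybar) - a_d ybar,
```

whose variation-of-constants solution `ybar_from_sbar()` evaluates by
trapezoidal quadrature (global accuracy O(dt^2); the integrating factor is
applied stepwise so long horizons cannot overflow). Note this closed form
factorizes `E[S(V)(1 - y)]` into `E[S(V)] (1 - E[y])`; the package treats it
as definitional for the limit system - as the fixed-point construction does -
and `picard_solve()` additionally reports the sup-norm gap between the
ensemble mean of `y` and the closed-form `ybar` (`ybar_gap` in `glance()`),
so the size of the neglected correlation is visible rather than assumed.

`picard_solve()` iterates the fixed-point map through those two functionals
only (laws are never stored as path measures): given `sbar`, compute `ybar`
in closed form; simulate `M` i.i.d. limit copies driven by that `ybar`;
extract the next empirical `sbar`. Iterations reuse the same seed (common
random numbers), making the map deterministic and its residuals directly
comparable; convergence is declared from the second iteration onwards, since
the first merely corrects the constant-in-time initial guess
`sbar(t) = E[S(V_0)]`. A damping factor on the `sbar` update is available for
stiff configurations (default 1, undamped). Non-convergence is an error that
carries the residual history.

## Measuring propagation of chaos

Propagation of chaos is quantified with a pathwise coupling: the N-neuron
network and N independent mean-field copies (one per neuron, same population)
are driven by the *same* Brownian increments and initial draws; in the
sign-preserving model the copies reuse the network's conductance paths
exactly. At `t = 0` the systems coincide; their subsequent distance

```
D_N = E[ sup_{t <= T} sum_alpha |R_t^{i_alpha, N} - Rtilde_t^{i_alpha}|^2 ]
```

(one tracked neuron per population; the state norm sums every lumped
component) measures the finite-size error. The mean-field theory bounds
`sqrt(N) * D_N` by a constant - slower than the `1/N` rate of globally
Lipschitz interactions, because the synaptic kernel is only locally
Lipschitz. `chaos_scan()` estimates `D_N` over a range of `N` by independent
replications, reports `sqrt(N) * D_N` and the log-log slope with a bootstrap
confidence interval, and reuses one high-accuracy mean-field solve
(`M >= 10 x max N`) across the scan, whose Monte-Carlo quality is reported
alongside so the bias floor is visible. The sup over continuous time is
approximated by the sup over every simulation step.

The per-replication statistic is heavy-tailed in excitable regimes: a
replicate in which the tracked neuron's network copy and limit copy fall on
different sides of a spike contributes an O(1) squared deviation, so a
32-replication mean can be dominated by a few such events and the
`sqrt(N) * D_N` profile is correspondingly noisy. This is a property of the
statistic under the reference configuration (neurons initialised across the
excitation threshold), not of the coupling construction; the fitted slope is
much more stable than the max/min ratio of `sqrt(N) * D_N`.

## Default parameters

The model structure fixes no numeric values; the package's defaults
are its own reference configuration and all are overridable:

| parameter | default | meaning / rationale |
|---|---|---|
| FHN `(a, b, c)` | (0.7, 0.8, 0.08) | classic FitzHugh recovery constants |
| HH conductances | `g_Na = 120, g_K = 36, g_L = 0.3` mS/cm^2 | classic squid-axon values, reversals 50 / -77 / -54.387 mV |
| `sigma_V` | 0.2 (FHN), 1.0 (HH) | moderate membrane noise |
| `a_r, a_d` | 1.0, 0.3 /ms | fast transmitter release, slower reuptake |
| sigmoid | `C = 1, lambda = 1, delta = 0` (FHN); `lambda = 0.2, delta = -30` (HH) | release saturating at 1, centred on the spiking range of each model |
| `Jbar, sigma_J, theta` | 0.5, 0.2, 0.5 | moderate coupling; CIR stationary sd well below the mean |
| `Vrev` | 1.0 (FHN), 0 mV (HH excitatory) | depolarising synapses |
| `chi` | trapezoid, 0 outside [0.05, 0.95], 1 on [0.1, 0.9] | Lipschitz (constant 20), compact support, noise unattenuated in the bulk |
| rate floor `nu` | 1e-3 /ms | coercivity floor on the HH gating rates |
| potential clip | [-100, 100] mV | rates evaluated on a bounded range, hence bounded Lipschitz |

Initial conditions (`init_law_spec()`): proportions `~ Beta(2,2)` rescaled
into [0.1, 0.9]; conductances `~ Gamma(mean = Jbar, shape = 4)` (strictly
positive); `V_0 ~ Normal(-60, 5)` mV for HH. For FHN populations the default
is `V_0 ~ Normal(0, 1)`, `w_0 ~ Normal(0, 0.5)`: the FHN membrane variable is
the usual dimensionless one living on the cubic nullcline in [-2.5, 2.5], and
a -60 mV initialisation there would sit on the cubic's steep branch where an
explicit Euler step at practical step sizes diverges immediately. This
choice scatters neurons around the excitation threshold, so early trajectories
include spike onsets - realistic for a perturbed network, but it makes
coupling statistics heavy-tailed (above).

## Numerical choices

* **Time stepping** - explicit Euler-Maruyama on a uniform grid, coefficients
  evaluated at the pre-step state. The strong order in the additive-noise
  membrane channel is ~1, in the multiplicative channels ~1/2; a shared-noise
  refinement test checks the observed order.
* **CIR discretisation** - full truncation: drift and diffusion evaluated at
  `max(J, 0)` and the result floored at 0. Positivity holds for any
  parameters, without a Feller condition.
* **Boundary policy** - no clamping by default. With the default envelope and
  `dt = 1e-4` every gate/synapse path stays in [0, 1]; at `dt = 1e-3` the
  Euler step can very occasionally jump through the 0.05-wide ramp of the
  envelope (excursions of order 1e-2 at per-sample frequency below 1e-3).
  Excursions are counted exactly at every step and reported
  (`excursion_stats()`); an optional post-step clamp exists behind a flag but
  is never silent.
* **Noise streams** - counter-based: every (neuron stream id, channel) pair
  owns a reproducible stream generated in fixed 2048-step blocks, so an
  increment depends only on (seed, stream id, channel, step index). This is
  what makes the coupling exact (both systems read the same streams),
  permutation tests bit-identical (streams travel with the neuron), and
  replicate batching equivalent to sequential runs. Population means are
  summed in stream-id order so floating-point addition is
  permutation-invariant. The diffusion interaction of the simple model and
  the CIR noise of the sign-preserving model draw from the same per-(neuron,
  target population) family, matching the one-Brownian-per-pair indexation of
  the network equations.
* **One-sided Lipschitz estimator** - grid supremum of
  `(F(v,q) - F(v',q))/(v - v') + M(v, v')`, excluding `|v - v'| < 1e-12`.
  The pairwise statistic carries rounding noise of order `ulp`; the supremum
  is reported at a 12-significant-digit noise floor, which is far below any
  grid-resolution effect. For the FitzHugh-Nagumo drift with damping form
  `M = (|v| - |v'|)^2 / 3` the supremum is 1, attained at pairs with
  `v v' = 0`.
* **Quadrature** - trapezoidal, stepwise integrating factor (O(dt^2)); the
  `ybar` output is clamped to [0, 1] against O(dt^2) overshoot at the
  endpoints.
* **Degenerate inputs** - zero coupling (`Jbar = sigma_J = 0`) is allowed and
  exercises exact identities (the coupled systems coincide bit-for-bit); a
  constant-zero conductance law stands in for the otherwise strictly positive
  initial conductances in that control.

## What the experiments do and do not show

The shipped experiments generate all data synthetically under the defaults
above: they demonstrate the boundary-confinement mechanism, the O(dt^2)
quadrature, the CIR mean relaxation, the exactness of the coupling under
zero interaction, and the decay of the coupling error with N on a
one-population FitzHugh-Nagumo network over a short horizon (T = 5,
dt = 1e-3, N up to 160, 32 replications - sizes chosen so the full suite
runs in minutes on one core). Passing them does not certify behaviour for
real cortical parameter ranges, long horizons, strong coupling, or the
classic HH drift's non-one-sided-Lipschitz regime (where the theory itself
needs localisation arguments); the HH estimate reported by
`validate_hypotheses()` is informational.

## Known limitations

* The simulator targets the Langevin approximation; exact (jump-process)
  channel simulation is out of scope, as are Fokker-Planck solvers and
  stationary-law computations.
* `D_N` estimates are heavy-tailed in excitable regimes (see above); compare
  slopes, not single ratios, when the replication budget is small.
* The mean-field input to the coupled limit copies is itself a Monte-Carlo
  object; its error enters `D_N` as a common bias, reported through the
  solver's `glance()`.
* Adaptive time stepping is not provided; choose `dt` against the fastest
  gating rate and the envelope ramp width.
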