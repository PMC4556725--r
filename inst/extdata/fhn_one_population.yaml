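# Reference configuration: one population of FitzHugh-Nagumo neurons with
# sign-preserving (CIR) maximal conductances. Units: mV, ms.
populations:
  exc:
    model_kind: fhn
    sigma_V: 0.2
    a_r: 1.0
    a_d: 0.3
    sigmoid: {C: 1.0, lambda: 1.0, delta: 0.0}
    fhn: {a: 0.7, b: 0.8, c: 0.08}
interactions:
  - {from: exc, to: exc, V_rev: 1.0, J_bar: 0.5, sigma_J: 0.2, theta: 0.5}
chi: {shape: trapezoid, lo: 0.05, hi: 0.95, peak: 1.0, ramp: 0.05}
proportions: {exc: 1.0}
conductance_model: sign_preserving
run: {T: 5.0, dt: 0.001, N: 100, seed: 1, stride: 1}
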