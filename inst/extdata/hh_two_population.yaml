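# Two Hodgkin-Huxley populations (excitatory / inhibitory) with
# sign-preserving conductances. Units: mV, ms.
populations:
  exc:
    model_kind: hh
    sigma_V: 1.0
    a_r: 1.0
    a_d: 0.3
    sigmoid: {C: 1.0, lambda: 0.2, delta: -30.0}
    hh: {g_Na: 120.0, E_Na: 50.0, g_K: 36.0, E_K: -77.0,
         g_L: 0.3, E_L: -54.387, C_m: 1.0, I_app: 5.0}
  inh:
    model_kind: hh
    sigma_V: 1.0
    a_r: 1.0
    a_d: 0.3
    sigmoid: {C: 1.0, lambda: 0.2, delta: -30.0}
    hh: {g_Na: 120.0, E_Na: 50.0, g_K: 36.0, E_K: -77.0,
         g_L: 0.3, E_L: -54.387, C_m: 1.0, I_app: 0.0}
interactions:
  - {from: exc, to: exc, V_rev: 0.0,   J_bar: 0.4, sigma_J: 0.2, theta: 0.5}
  - {from: exc, to: inh, V_rev: -80.0, J_bar: 0.6, sigma_J: 0.2, theta: 0.5}
  - {from: inh, to: exc, V_rev: 0.0,   J_bar: 0.4, sigma_J: 0.2, theta: 0.5}
  - {from: inh, to: inh, V_rev: -80.0, J_bar: 0.3, sigma_J: 0.2, theta: 0.5}
chi: {shape: trapezoid, lo: 0.05, hi: 0.95, peak: 1.0, ramp: 0.05}
proportions: {exc: 0.8, inh: 0.2}
conductance_model: sign_preserving
run: {T: 5.0, dt: 0.0005, N: 50, seed: 1, stride: 10}
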