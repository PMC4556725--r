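# Shared fixture builders: everything is generated in code.

fhn1 <- function(...) fhn_model_spec(...)

fhn_uncoupled <- function() {
  fhn_model_spec(J_bar = 0, sigma_J = 0, theta = 0.5)
}

fhn2 <- function(...) {
  # two FHN populations, equal proportions, asymmetric coupling
  pops <- list(fhn_population("a"), fhn_population("b", sigma_V = 0.3))
  inter <- dplyr::bind_rows(
    interaction_spec("a", "a", V_rev = 1, J_bar = 0.4, sigma_J = 0.2, theta = 0.5),
    interaction_spec("a", "b", V_rev = -1, J_bar = 0.3, sigma_J = 0.2, theta = 0.5),
    interaction_spec("b", "a", V_rev = 1, J_bar = 0.2, sigma_J = 0.1, theta = 0.5),
    interaction_spec("b", "b", V_rev = -1, J_bar = 0.1, sigma_J = 0.1, theta = 0.5)
  )
  model_spec(pops, inter, proportions = c(a = 0.5, b = 0.5), ...)
}

hh1 <- function(...) hh_model_spec(...)

# deterministic single-neuron state builders
state1 <- function(model, V = 0.5, y = 0.3, w = 0.1, J = NULL) {
  p <- model$p_bar
  if (model$conductance_model == "sign_preserving" && is.null(J)) {
    J <- matrix(0.5, 1, p)
  }
  network_state(0, 1L, 1L, V, y, w, J = J)
}

zero_increments <- function(n, p, hh = FALSE) {
  out <- list(V = numeric(n), y = numeric(n), B = matrix(0, n, p))
  if (hh) out$n <- out$m <- out$h <- numeric(n)
  out
}
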