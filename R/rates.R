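# Classic Hodgkin-Huxley voltage-dependent opening (rho) and closing (zeta)
# rates for the gating variables n, m, h, in ms^-1, with membrane potential in
# mV (modern convention, resting potential near -65 mV).
#
# Two regularisations make the rates fit the structural hypotheses of the
# mean-field analysis: the potential is clipped to [-100, 100] mV before
# evaluation, so every rate is a bounded Lipschitz function on the whole real
# line, and the rates are floored at `floor_rate` so that
# rho_x(v) ^ zeta_x(v) >= nu > 0 (the coercivity needed for the mean-field
# limit to be well posed).

# x/(1 - exp(-x/s)) with the removable singularity at x = 0 filled in
.vtrap <- function(x, s) {
  out <- x / (1 - exp(-x / s))
  small <- abs(x / s) < 1e-7
  out[small] <- s * (1 + x[small] / (2 * s))
  out
}

.hh_rate_funs <- function(v_clip = c(-100, 100), floor_rate = 1e-3) {
  clipf <- function(v) pmin(pmax(v, v_clip[1]), v_clip[2])
  flo <- function(r) pmax(r, floor_rate)
  list(
    n = list(
      rho  = function(v) { v <- clipf(v); flo(0.01 * .vtrap(v + 55, 10)) },
      zeta = function(v) { v <- clipf(v); flo(0.125 * exp(-(v + 65) / 80)) }
    ),
    m = list(
      rho  = function(v) { v <- clipf(v); flo(0.1 * .vtrap(v + 40, 10)) },
      zeta = function(v) { v <- clipf(v); flo(4 * exp(-(v + 65) / 18)) }
    ),
    h = list(
      rho  = function(v) { v <- clipf(v); flo(0.07 * exp(-(v + 65) / 20)) },
      zeta = function(v) { v <- clipf(v); flo(1 / (1 + exp(-(v + 35) / 10))) }
    )
  )
}
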