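#' Initial-condition laws
#'
#' Small law descriptors for initial conditions. Neurons within a population
#' are i.i.d.; each neuron's draw comes from its own counter-based substream,
#' so initial conditions are reproducible per (seed, stream id) and invariant
#' under batching.
#'
#' Supports required by the model structure: synaptic and gating proportions
#' must live in \[0, 1\]; conductances in `[0, +Inf)` with strictly positive
#' support in any non-degenerate configuration; potentials need all moments
#' finite (every family here has them).
#'
#' @param mean,sd,min,max,shape1,shape2,lo,hi,shape,value family parameters.
#' @return a law descriptor (class `nm_law`).
#' @name laws
NULL

.new_law <- function(dist, ...) {
  structure(c(list(dist = dist), list(...)), class = "nm_law")
}

#' @rdname laws
#' @export
law_normal <- function(mean, sd) {
  stopifnot(sd >= 0)
  .new_law("normal", mean = mean, sd = sd)
}

#' @rdname laws
#' @export
law_uniform <- function(min, max) {
  stopifnot(min <= max)
  .new_law("uniform", min = min, max = max)
}

#' @rdname laws
#' @description `law_beta()` is a Beta(shape1, shape2) rescaled affinely onto
#'   `[lo, hi]`.
#' @export
law_beta <- function(shape1 = 2, shape2 = 2, lo = 0.1, hi = 0.9) {
  stopifnot(shape1 > 0, shape2 > 0, lo < hi)
  .new_law("beta_scaled", shape1 = shape1, shape2 = shape2, lo = lo, hi = hi)
}

#' @rdname laws
#' @description `law_gamma()` is parameterised by its mean and shape
#'   (rate = shape / mean); support `(0, +Inf)`.
#' @export
law_gamma <- function(mean, shape = 4) {
  stopifnot(mean > 0, shape > 0)
  .new_law("gamma", mean = mean, shape = shape)
}

#' @rdname laws
#' @export
law_const <- function(value) .new_law("constant", value = value)

.law_sample <- function(law, n) {
  if (!inherits(law, "nm_law")) abort("not a law object")
  switch(law$dist,
    normal = rnorm(n, law$mean, law$sd),
    uniform = runif(n, law$min, law$max),
    beta_scaled = law$lo + (law$hi - law$lo) * rbeta(n, law$shape1, law$shape2),
    gamma = rgamma(n, shape = law$shape, rate = law$shape / law$mean),
    constant = rep_len(law$value, n),
    abort(sprintf("unsupported law family '%s'", law$dist))
  )
}

.check_unit_law <- function(law, what) {
  ok <- switch(law$dist,
    uniform = law$min >= 0 && law$max <= 1,
    beta_scaled = law$lo >= 0 && law$hi <= 1,
    constant = law$value >= 0 && law$value <= 1,
    FALSE)
  if (!ok) {
    abort(sprintf("law for %s must have support inside [0, 1] (got family '%s')",
                  what, law$dist))
  }
}

.check_pos_law <- function(law, what) {
  ok <- switch(law$dist,
    gamma = TRUE,
    uniform = law$min >= 0,
    constant = law$value >= 0,
    FALSE)
  if (!ok) {
    abort(sprintf("law for %s must have support in [0, +Inf) (got family '%s')",
                  what, law$dist))
  }
}

#' Initial-condition law specification for a model
#'
#' Builds the per-population initial laws, with overridable defaults:
#' potentials `V0 ~ Normal(-60, 5)` mV for Hodgkin-Huxley populations and
#' `Normal(0, 1)` for FitzHugh-Nagumo (whose membrane variable is the usual
#' dimensionless one living on the cubic nullcline); synaptic and gating
#' proportions `~ Beta(2, 2)` rescaled into `[0.1, 0.9]`; recovery
#' `w0 ~ Normal(0, 0.5)`; conductances `J0 ~ Gamma(mean = J_bar, shape = 4)`
#' per target population (degenerate at 0 when `J_bar = 0`, the uncoupled
#' control).
#'
#' @param model an [model_spec()].
#' @param overrides named list: `overrides[[label]]` is a list with any of
#'   `V0`, `y0`, `w0`, `n0`, `m0`, `h0` (law objects) and `J0` (a named list
#'   of laws per target population label, or one law recycled to all).
#' @return an object of class `nm_init_laws`.
#' @export
init_law_spec <- function(model, overrides = list()) {
  stopifnot(inherits(model, "nm_model"))
  laws <- list()
  for (ai in seq_along(model$labels)) {
    lab <- model$labels[ai]
    pop <- model$populations[[ai]]
    l <- list(
      V0 = if (pop$model_kind == "hh") law_normal(-60, 5) else law_normal(0, 1),
      y0 = law_beta(),
      w0 = law_normal(0, 0.5),
      n0 = law_beta(), m0 = law_beta(), h0 = law_beta()
    )
    if (model$conductance_model == "sign_preserving") {
      jb <- model$interactions
      l$J0 <- lapply(setNames(model$labels, model$labels), function(g) {
        jbar <- jb$J_bar[jb$from == lab & jb$to == g]
        if (jbar > 0) law_gamma(mean = jbar, shape = 4) else law_const(0)
      })
    }
    ov <- overrides[[lab]]
    if (!is.null(ov)) {
      for (f in intersect(names(ov), c("V0", "y0", "w0", "n0", "m0", "h0"))) {
        l[[f]] <- ov[[f]]
      }
      if (!is.null(ov$J0)) {
        if (inherits(ov$J0, "nm_law")) {
          l$J0 <- lapply(l$J0, function(...) ov$J0)
        } else {
          for (g in names(ov$J0)) l$J0[[g]] <- ov$J0[[g]]
        }
      }
    }
    for (f in c("y0", "n0", "m0", "h0")) .check_unit_law(l[[f]], paste0(lab, "$", f))
    if (!is.null(l$J0)) for (g in names(l$J0)) .check_pos_law(l$J0[[g]], paste0(lab, "$J0$", g))
    laws[[lab]] <- l
  }
  structure(list(laws = laws, labels = model$labels,
                 conductance_model = model$conductance_model),
            class = "nm_init_laws")
}

#' Sample i.i.d. initial conditions
#'
#' One draw per neuron from its population's initial laws, through the
#' neuron's own substream: identical `(seed, stream id)` always yields the
#' identical draw, regardless of how many other neurons are present.
#'
#' @param model an [model_spec()].
#' @param laws an [init_law_spec()]; defaults are built from the model.
#' @param layout an [population_layout()].
#' @param seed integer seed.
#' @return an [network_state()] at `t = 0`.
#' @export
sample_initial_conditions <- function(model, laws = NULL, layout, seed) {
  stopifnot(inherits(model, "nm_model"), inherits(layout, "nm_layout"))
  if (is.null(laws)) laws <- init_law_spec(model)
  stopifnot(inherits(laws, "nm_init_laws"))
  N <- layout$N
  p <- model$p_bar
  V <- y <- w <- gn <- gm <- gh <- numeric(N)
  J <- if (model$conductance_model == "sign_preserving") matrix(0, N, p) else NULL
  for (i in seq_len(N)) {
    set.seed(.mix_seed(seed, layout$stream_id[i], .CH[["init"]], 0L))
    l <- laws$laws[[layout$assignment[i]]]
    V[i] <- .law_sample(l$V0, 1)
    y[i] <- .law_sample(l$y0, 1)
    kind <- model$populations[[layout$assignment[i]]]$model_kind
    if (kind == "fhn") {
      w[i] <- .law_sample(l$w0, 1)
    } else {
      gn[i] <- .law_sample(l$n0, 1)
      gm[i] <- .law_sample(l$m0, 1)
      gh[i] <- .law_sample(l$h0, 1)
    }
    if (!is.null(J)) {
      for (g in seq_len(p)) J[i, g] <- .law_sample(l$J0[[g]], 1)
    }
  }
  network_state(0, layout$assignment, layout$stream_id,
                V, y, w, gn, gm, gh, J)
}
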