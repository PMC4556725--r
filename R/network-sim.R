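#' Assign neurons to populations
#'
#' Splits `N` neurons over the model's populations according to the fixed
#' proportions `c_gamma`, in contiguous blocks. `N * c_gamma` must be a whole
#' number for every population - the proportions are a structural constant of
#' the limit, not a rounding suggestion.
#'
#' @param model an [model_spec()] object.
#' @param N total number of neurons.
#' @param stream_id optional integer vector of noise stream identifiers, one
#'   per neuron (default `1:N`). Streams, not storage positions, identify a
#'   neuron's randomness; permuting neurons together with their stream ids
#'   reproduces a run exactly.
#' @return an object of class `nm_layout` with fields `assignment` (population
#'   index per neuron), `counts`, `N`, `labels`, `stream_id`.
#' @export
population_layout <- function(model, N, stream_id = NULL) {
  stopifnot(inherits(model, "nm_model"), N >= 1)
  counts <- model$proportions * N
  if (any(abs(counts - round(counts)) > 1e-9)) {
    abort(sprintf(
      "N = %d is incompatible with the fixed proportions (%s): every N * c_gamma must be an integer",
      N, paste(sprintf("%s = %g", model$labels, model$proportions), collapse = ", ")))
  }
  counts <- as.integer(round(counts))
  if (any(counts < 1L)) abort("every population needs at least one neuron")
  assignment <- rep(seq_along(counts), counts)
  if (is.null(stream_id)) stream_id <- seq_len(N)
  stopifnot(length(stream_id) == N, !anyDuplicated(stream_id))
  structure(
    list(assignment = assignment, counts = setNames(counts, model$labels),
         N = as.integer(N), labels = model$labels,
         stream_id = as.integer(stream_id)),
    class = "nm_layout"
  )
}

#' Construct a network state
#'
#' @param t time (ms).
#' @param pop population index per neuron.
#' @param stream_id noise stream id per neuron.
#' @param V,y numeric vectors (potential, synaptic proportion).
#' @param w recovery variable (FHN; 0 where unused).
#' @param n,m,h gating variables (HH; 0 where unused).
#' @param J `N x p` matrix of per-neuron conductances towards each target
#'   population (sign-preserving model), or `NULL`.
#' @return an object of class `nm_state`.
#' @export
network_state <- function(t, pop, stream_id, V, y, w = NULL,
                          n = NULL, m = NULL, h = NULL, J = NULL) {
  N <- length(V)
  zero <- function(x) if (is.null(x)) numeric(N) else x
  stopifnot(length(y) == N, length(pop) == N, length(stream_id) == N)
  structure(
    list(t = t, pop = as.integer(pop), stream_id = as.integer(stream_id),
         V = V, y = y, w = zero(w), gn = zero(n), gm = zero(m), gh = zero(h),
         J = J),
    class = "nm_state"
  )
}

#' Empirical synaptic input from one population
#'
#' The interaction functional of the finite network: the average
#' `(1/N_gamma) * sum over neurons j in population gamma of y_j`, i.e. the
#' mean available-neurotransmitter proportion presented to every postsynaptic
#' neuron by population `gamma`. This is the quantity that converges to
#' `E[y_t^gamma]` in the mean-field limit.
#'
#' @param state an [network_state()].
#' @param layout an [population_layout()].
#' @param gamma a population label.
#' @return the mean proportion, in `[0, 1]`.
#' @export
population_synaptic_input <- function(state, layout, gamma) {
  gi <- match(gamma, layout$labels)
  if (is.na(gi)) abort(sprintf("unknown population label '%s'", gamma))
  idx <- which(layout$assignment == gi)
  if (!length(idx)) abort(sprintf("population '%s' has no neurons", gamma))
  idx <- idx[order(state$stream_id[idx])]  # canonical summation order
  sum(state$y[idx]) / length(idx)
}

#' One step of a Cox-Ingersoll-Ross conductance
#'
#' Full-truncation Euler step for
#' `dJ = theta (J_bar - J) dt + sigma_J sqrt(J) dB`:
#' drift and diffusion are evaluated at `max(J, 0)` and the result is floored
#' at 0, so conductances remain non-negative without a Feller-type restriction
#' on the parameters. With `sigma_J = 0` the step reduces to the deterministic
#' relaxation `J + theta (J_bar - J) dt`.
#'
#' @param J current conductance(s), `>= 0`.
#' @param theta reversion rate (ms^-1).
#' @param J_bar long-run mean.
#' @param sigma_J noise intensity.
#' @param dt time step (ms, > 0).
#' @param dB Brownian increment(s) over the step (i.e. `N(0, dt)` variates).
#' @return the next conductance value(s), `>= 0`.
#' @export
cir_step <- function(J, theta, J_bar, sigma_J, dt, dB) {
  if (dt <= 0) abort("dt must be > 0")
  if (any(J < 0)) abort("cir_step: negative input conductance (invariant breach upstream)")
  Jp <- pmax(J, 0)
  pmax(J + theta * (J_bar - Jp) * dt + sigma_J * sqrt(Jp) * dB, 0)
}

#' One Euler-Maruyama step of the full network
#'
#' Advances every neuron by one explicit Euler-Maruyama step: the membrane
#' potential with its drift, the synaptic interaction (empirical population
#' means of `y`, scaled by the mean conductance in the simple model or by the
#' per-neuron CIR conductances in the sign-preserving model), the synaptic
#' and gating variables with their square-root Langevin coefficients, and the
#' recovery variable or conductances.
#'
#' @param state an [network_state()].
#' @param model an [model_spec()].
#' @param layout an [population_layout()].
#' @param dt time step (ms).
#' @param increments list of standard-normal increments for this step:
#'   vectors `V`, `y` (and `n`, `m`, `h` for HH) of length `N`, and an
#'   `N x p` matrix `B`. They are scaled by `sqrt(dt)` internally.
#' @param clamp if `TRUE`, clamp proportion variables to `[0, 1]` after the
#'   step (off by default: the vanishing diffusion and inward drift keep paths
#'   inside at small `dt`, and excursions are meant to be observed, not
#'   silently fixed).
#' @return the next [network_state()].
#' @export
step_network <- function(state, model, layout, dt, increments, clamp = FALSE) {
  stopifnot(inherits(state, "nm_state"), inherits(model, "nm_model"))
  par <- .sys_params(model, state$pop)
  ms <- .mean_structure(state$pop, state$stream_id, rep(1L, par$n), par$p)
  ybar_eff <- .empirical_ybar(state$y, ms, rep(1L, par$n), par$n, par$p)
  dW <- increments
  if (is.null(dW$B)) dW$B <- matrix(0, par$n, par$p)
  if (!is.matrix(dW$B)) dW$B <- matrix(dW$B, par$n, par$p)
  st <- .system_step(state[c("V", "y", "w", "gn", "gm", "gh", "J")], par,
                     dt, sqrt(dt), dW, ybar_eff, clamp = clamp)
  .check_finite(st, step = 1L)
  network_state(state$t + dt, state$pop, state$stream_id,
                st$V, st$y, st$w, st$gn, st$gm, st$gh, st$J)
}

# core trajectory runner shared by simulate_network and the mean-field
# ensemble; mode "network" uses empirical population means, mode "limit"
# reads the prescribed ybar path.
.run_particles <- function(model, pop_idx, stream_id, group, state0,
                           nsteps, dt, seed, stride = 1L,
                           mode = c("network", "limit"), ybar_path = NULL,
                           clamp = FALSE, increments = NULL,
                           track_sbar = FALSE) {
  mode <- match.arg(mode)
  par <- .sys_params(model, pop_idx, group)
  n <- par$n; p <- par$p
  sdt <- sqrt(dt)
  ms <- if (mode == "network") .mean_structure(pop_idx, stream_id, group, p) else NULL

  st <- state0[c("V", "y", "w", "gn", "gm", "gh", "J")]
  exc_vars <- c("y", if (par$any_hh) c("n", "m", "h"))
  exc <- .exc_init(exc_vars, n)
  exc <- .exc_update(exc, .exc_vals(st, par))

  nsnap <- nsteps %/% stride + 1L
  snap <- list(V = matrix(NA_real_, nsnap, n), y = matrix(NA_real_, nsnap, n),
               w = matrix(NA_real_, nsnap, n))
  if (par$any_hh) {
    snap$gn <- matrix(NA_real_, nsnap, n)
    snap$gm <- matrix(NA_real_, nsnap, n)
    snap$gh <- matrix(NA_real_, nsnap, n)
  }
  if (!is.null(st$J)) snap$J <- array(NA_real_, c(nsnap, n, p))
  put <- function(row, st) {
    snap$V[row, ] <<- st$V; snap$y[row, ] <<- st$y; snap$w[row, ] <<- st$w
    if (par$any_hh) {
      snap$gn[row, ] <<- st$gn; snap$gm[row, ] <<- st$gm; snap$gh[row, ] <<- st$gh
    }
    if (!is.null(st$J)) snap$J[row, , ] <<- st$J
  }
  put(1L, st)

  if (track_sbar) {
    sbar <- matrix(NA_real_, nsteps + 1L, p)
    ybar_emp <- matrix(NA_real_, nsteps + 1L, p)
    pop_slices <- lapply(seq_len(p), function(g) which(pop_idx == g))
    rec <- function(k, st) {
      s <- .sigmoid_vec(par, st$V)
      for (g in seq_len(p)) {
        sbar[k, g] <<- mean(s[pop_slices[[g]]])
        ybar_emp[k, g] <<- mean(st$y[pop_slices[[g]]])
      }
    }
    rec(1L, st)
  }

  step <- 0L
  chunk <- 0L
  while (step < nsteps) {
    len <- min(.CHUNK_STEPS, nsteps - step)
    chm <- .chunk_increments(seed, stream_id, par, chunk, len, increments)
    for (k in seq_len(len)) {
      ybar_eff <- if (mode == "network") {
        .empirical_ybar(st$y, ms, group, n, p)
      } else {
        matrix(ybar_path[step + k, ], nrow = n, ncol = p, byrow = TRUE)
      }
      st <- .system_step(st, par, dt, sdt, .dW_at(chm, k, par, n),
                         ybar_eff, clamp = clamp)
      gstep <- step + k
      exc <- .exc_update(exc, .exc_vals(st, par))
      if (gstep %% stride == 0L) put(gstep %/% stride + 1L, st)
      if (track_sbar) rec(gstep + 1L, st)
    }
    step <- step + len
    chunk <- chunk + 1L
    .check_finite(st, step)
  }

  list(par = par, snap = snap, final = st, exc = .exc_table(exc),
       sbar = if (track_sbar) sbar else NULL,
       ybar_emp = if (track_sbar) ybar_emp else NULL)
}

.exc_vals <- function(st, par) {
  v <- list(y = st$y)
  if (par$any_hh) { v$n <- st$gn; v$m <- st$gm; v$h <- st$gh }
  v
}

#' Simulate the N-neuron network
#'
#' Runs the interacting particle system with explicit Euler-Maruyama stepping
#' on a uniform grid. The run is fully reproducible from
#' `(model, init, seed, dt, stride)`; noise increments are drawn from
#' counter-based streams indexed by `(seed, neuron stream id, channel)`.
#'
#' @param model an [model_spec()].
#' @param layout an [population_layout()].
#' @param init an [network_state()] at `t = 0`, e.g. from
#'   [sample_initial_conditions()].
#' @param T time horizon (ms); `T / dt` must be a whole number.
#' @param dt time step (ms).
#' @param seed integer seed.
#' @param stride store every `stride`-th step (snapshots at `0, stride * dt,
#'   ...`). Excursion statistics are nevertheless accumulated at every step.
#' @param clamp see [step_network()].
#' @param .increments advanced: caller-supplied standard-normal increment
#'   arrays (`nsteps x N` matrices `V`, `y`, ..., list `B`), for shared-noise
#'   refinement studies. Overrides the stream generator.
#' @return an object of class `nm_trajectory`: snapshot matrices per variable,
#'   the time grid, per-variable excursion statistics over all steps
#'   (tibble `excursions`), and provenance. Use [as_tibble()] for a long
#'   tidy view, [excursion_stats()] for boundary bookkeeping.
#' @examples
#' m <- fhn_model_spec(J_bar = 0, sigma_J = 0)
#' lay <- population_layout(m, 4)
#' init <- sample_initial_conditions(m, layout = lay, seed = 1)
#' tr <- simulate_network(m, lay, init, T = 1, dt = 1e-3, seed = 1, stride = 100)
#' dplyr::glimpse(tibble::as_tibble(tr))
#' @export
simulate_network <- function(model, layout, init, T, dt, seed, stride = 1L,
                             clamp = FALSE, .increments = NULL) {
  stopifnot(inherits(model, "nm_model"), inherits(layout, "nm_layout"),
            inherits(init, "nm_state"))
  nsteps <- T / dt
  if (abs(nsteps - round(nsteps)) > 1e-8) abort("T / dt must be an integer")
  nsteps <- as.integer(round(nsteps))
  if (model$conductance_model == "sign_preserving" && is.null(init$J)) {
    abort("sign-preserving model: initial state needs conductances J")
  }
  res <- .run_particles(model, init$pop, init$stream_id,
                        rep(1L, layout$N), init, nsteps, dt, seed,
                        stride = as.integer(stride), mode = "network",
                        clamp = clamp, increments = .increments)
  .new_trajectory(res, model, times = seq(0, nsteps, by = stride) * dt,
                  seed = seed, dt = dt, stride = stride,
                  stream_id = init$stream_id)
}

.new_trajectory <- function(res, model, times, seed, dt, stride,
                            stream_id = NULL) {
  structure(
    list(times = times, pop = res$par$pop_idx, labels = model$labels,
         stream_id = stream_id, V = res$snap$V, y = res$snap$y, w = res$snap$w,
         n = res$snap$gn, m = res$snap$gm, h = res$snap$gh, J = res$snap$J,
         final = res$final, excursions = res$exc,
         provenance = list(seed = seed, dt = dt, stride = stride,
                           scheme = "euler-maruyama",
                           conductance_model = model$conductance_model)),
    class = "nm_trajectory"
  )
}

#' @export
print.nm_trajectory <- function(x, ...) {
  cat(sprintf("<nm_trajectory> %d neurons, %d snapshots on [0, %g] ms (dt = %g, stride = %d)\n",
              ncol(x$V), length(x$times), max(x$times),
              x$provenance$dt, x$provenance$stride))
  invisible(x)
}

#' @method as_tibble nm_trajectory
#' @export
as_tibble.nm_trajectory <- function(x, ...) {
  n <- ncol(x$V)
  base <- function(varname, mat) {
    tibble(time = rep(x$times, n),
           neuron = rep(seq_len(n), each = length(x$times)),
           population = rep(x$labels[x$pop], each = length(x$times)),
           variable = varname, value = as.vector(mat))
  }
  out <- list(base("V", x$V), base("y", x$y), base("w", x$w))
  if (!is.null(x$n)) {
    out <- c(out, list(base("n", x$n), base("m", x$m), base("h", x$h)))
  }
  if (!is.null(x$J)) {
    for (g in seq_along(x$labels)) {
      out <- c(out, list(base(paste0("J.", x$labels[g]), x$J[, , g])))
    }
  }
  bind_rows(out)
}

#' Export a trajectory to CSV
#'
#' Long-format export (`time`, `neuron`, `population`, `variable`, `value`)
#' for small runs.
#'
#' @param traj an `nm_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(as_tibble(traj), path, row.names = FALSE)
  invisible(path)
}

#' @method autoplot nm_trajectory
#' @export
autoplot.nm_trajectory <- function(object, variable = "V", neurons = NULL, ...) {
  df <- as_tibble(object)
  df <- df[df$variable == variable, ]
  if (!is.null(neurons)) df <- df[df$neuron %in% neurons, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   group = .data$neuron,
                                   colour = .data$population)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "time (ms)", y = variable) +
    ggplot2::theme_minimal()
}
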