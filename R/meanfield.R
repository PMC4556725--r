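#' Mean synaptic proportion from the mean release path
#'
#' The expected synaptic proportion of the mean-field limit solves the linear
#' equation `dybar/dt = a_r sbar(t) (1 - ybar) - a_d ybar`, whose
#' variation-of-constants solution in the integrated release
#' `integral of sbar` is the closed form used throughout the fixed-point
#' construction (the synaptic diffusion plays no role in the mean). This
#' function evaluates that closed form by composite trapezoidal quadrature,
#' stepwise in the integrating factor so arbitrarily long horizons cannot
#' overflow: global accuracy is O(dt^2).
#'
#' @param a_r,a_d synaptic rise/decay rates (ms^-1).
#' @param y0_mean initial mean `E[y_0]`, in `[0, 1]`.
#' @param sbar numeric vector: the mean release path `E[S(V_t)] >= 0` on
#'   `times`.
#' @param times increasing time grid (ms), same length as `sbar`.
#' @return numeric vector `ybar` on `times`, valued in `[0, 1]`.
#' @examples
#' tt <- seq(0, 5, by = 1e-3)
#' ybar_from_sbar(1, 0.3, 0.2, rep(0.5, length(tt)), tt)[length(tt)]
#' @export
ybar_from_sbar <- function(a_r, a_d, y0_mean, sbar, times) {
  stopifnot(length(sbar) == length(times), length(times) >= 1L)
  if (any(sbar < 0)) abort("sbar must be non-negative")
  if (y0_mean < 0 || y0_mean > 1) abort("y0_mean must lie in [0, 1]")
  n <- length(times)
  y <- numeric(n)
  y[1] <- y0_mean
  if (n == 1L) return(y)
  h <- diff(times)
  if (any(h <= 0)) abort("times must be strictly increasing")
  f <- a_r * sbar
  for (k in seq_len(n - 1L)) {
    dG <- a_d * h[k] + h[k] * (f[k] + f[k + 1]) / 2
    Ek <- exp(-dG)
    y[k + 1] <- Ek * y[k] + h[k] / 2 * (f[k] * Ek + f[k + 1])
  }
  pmin(pmax(y, 0), 1)
}

.meanfield_matrix <- function(meanfield, labels, col, nrow_expect = NULL) {
  stopifnot(all(c("time", "population", col) %in% names(meanfield)))
  wide <- tidyr::pivot_wider(meanfield[c("time", "population", col)],
                             names_from = "population",
                             values_from = dplyr::all_of(col))
  wide <- arrange(wide, .data$time)
  miss <- setdiff(labels, names(wide))
  if (length(miss)) {
    abort(sprintf("mean-field paths lack population(s): %s",
                  paste(miss, collapse = ", ")))
  }
  m <- as.matrix(wide[labels])
  if (!is.null(nrow_expect) && nrow(m) != nrow_expect) {
    abort(sprintf("mean-field grid (%d points) does not match the simulation grid (%d points)",
                  nrow(m), nrow_expect))
  }
  list(times = wide$time, m = m)
}

#' Simulate an ensemble of i.i.d. mean-field limit copies
#'
#' Runs `M` independent copies per population of the decoupled limit SDEs, in
#' which the interaction enters only through the prescribed deterministic
#' path `ybar_gamma(t)` (in place of `E[y_t^gamma]`). In the sign-preserving
#' model each copy carries its own CIR conductances; in the simple model the
#' interaction also drives a diffusion term scaled by `sigma_J ybar`.
#'
#' @param model an [model_spec()].
#' @param meanfield a tibble with columns `time`, `population`, `ybar`
#'   (e.g. from [picard_solve()]), on the simulation grid `0, dt, ..., T`.
#' @param M copies per population.
#' @param dt time step (ms); the grid is taken from `meanfield`.
#' @param seed integer seed; copies are driven by independent streams.
#' @param laws an [init_law_spec()] (defaults built from the model).
#' @param stride snapshot stride for the stored trajectory.
#' @param stream_offset advanced: offset added to the copies' stream ids (used
#'   by the coupling construction, where copies share the network's streams).
#' @return an object of class `nm_ensemble`: the stored trajectory, the
#'   empirical per-step release path `sbar_hat` and mean synaptic path
#'   `ybar_hat` (matrices, one column per population), and `M`. Use
#'   [ensemble_estimates()] for a tidy view with standard errors.
#' @export
simulate_limit_ensemble <- function(model, meanfield, M, dt, seed,
                                    laws = NULL, stride = 1L,
                                    stream_offset = 0L) {
  stopifnot(inherits(model, "nm_model"), M >= 2)
  p <- model$p_bar
  mf <- .meanfield_matrix(meanfield, model$labels, "ybar")
  nsteps <- nrow(mf$m) - 1L
  if (nsteps < 1L) abort("mean-field path needs at least two grid points")
  if (max(abs(diff(mf$times) - dt)) > 1e-9) {
    abort("mean-field grid spacing does not equal dt")
  }
  pop_idx <- rep(seq_len(p), each = M)
  stream_id <- seq_len(M * p) + stream_offset
  lay <- structure(list(assignment = pop_idx,
                        counts = setNames(rep(M, p), model$labels),
                        N = as.integer(M * p), labels = model$labels,
                        stream_id = as.integer(stream_id)),
                   class = "nm_layout")
  init <- sample_initial_conditions(model, laws, lay, seed)
  res <- .run_particles(model, pop_idx, stream_id, rep(1L, M * p), init,
                        nsteps, dt, seed, stride = as.integer(stride),
                        mode = "limit", ybar_path = mf$m, track_sbar = TRUE)
  traj <- .new_trajectory(res, model,
                          times = seq(0, nsteps, by = stride) * dt,
                          seed = seed, dt = dt, stride = stride,
                          stream_id = stream_id)
  structure(
    list(traj = traj, sbar = res$sbar, ybar_emp = res$ybar_emp,
         times = mf$times, M = M, labels = model$labels,
         ybar_input = mf$m),
    class = "nm_ensemble"
  )
}

#' @export
print.nm_ensemble <- function(x, ...) {
  cat(sprintf("<nm_ensemble> %d copies x %d population(s) on [0, %g] ms\n",
              x$M, length(x$labels), max(x$times)))
  invisible(x)
}

#' Tidy estimates from a mean-field ensemble
#'
#' @param ens an [simulate_limit_ensemble()] result.
#' @return tibble with `time`, `population`, the empirical release path
#'   `sbar_hat` and the empirical mean synaptic path `ybar_hat`; the
#'   Monte-Carlo standard error of either mean scales as `1/sqrt(M)`.
#' @export
ensemble_estimates <- function(ens) {
  stopifnot(inherits(ens, "nm_ensemble"))
  bind_rows(lapply(seq_along(ens$labels), function(g) {
    tibble(time = ens$times, population = ens$labels[g],
           sbar_hat = ens$sbar[, g], ybar_hat = ens$ybar_emp[, g])
  }))
}

#' Solve the mean-field limit by Monte-Carlo Picard iteration
#'
#' Implements the fixed-point map on laws through the only functionals the
#' drift needs - the per-population mean release path
#' `sbar_alpha(t) = E[S_alpha(V_t^alpha)]` and mean synaptic path
#' `ybar_alpha(t) = E[y_t^alpha]`. Each iteration (i) converts the current
#' `sbar` into `ybar` by the closed form ([ybar_from_sbar()]), (ii) simulates
#' `M` i.i.d. limit copies per population driven by that `ybar`
#' ([simulate_limit_ensemble()]) under common random numbers, and (iii)
#' extracts the next empirical `sbar`. The iteration is a deterministic map
#' given the seed; it stops when the sup-norm change of `(sbar, ybar)` falls
#' below `tol`.
#'
#' @param model an [model_spec()].
#' @param T horizon (ms); `T/dt` must be an integer.
#' @param dt time step (ms).
#' @param M Monte-Carlo copies per population.
#' @param tol sup-norm convergence tolerance on `(sbar, ybar)`.
#' @param max_iter maximum Picard iterations; non-convergence is an error
#'   carrying the residual history (condition class
#'   `mfneuron_picard_nonconvergence`).
#' @param seed integer seed (held fixed across iterations: common random
#'   numbers).
#' @param laws an [init_law_spec()].
#' @param damping damping factor on the `sbar` update (1 = undamped).
#' @return an object of class `nm_meanfield`: a tibble `(time, population,
#'   sbar, ybar)` with attributes `iterations`, `residuals` (per-iteration
#'   sup-norm changes), `ybar_gap` (sup discrepancy between the ensemble mean
#'   of `y` and the closed-form `ybar` - reported, not asserted), `M`, `dt`
#'   and `seed`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
picard_solve <- function(model, T, dt, M = 1000, tol = 1e-3, max_iter = 12,
                         seed = 1, laws = NULL, damping = 1) {
  stopifnot(inherits(model, "nm_model"), tol > 0, max_iter >= 1)
  nsteps <- T / dt
  if (abs(nsteps - round(nsteps)) > 1e-8) abort("T / dt must be an integer")
  nsteps <- as.integer(round(nsteps))
  times <- seq(0, nsteps) * dt
  p <- model$p_bar
  if (is.null(laws)) laws <- init_law_spec(model)

  # initial functionals from the initial law (sbar constant in t)
  lay0 <- structure(list(assignment = rep(seq_len(p), each = M),
                         counts = setNames(rep(M, p), model$labels),
                         N = as.integer(M * p), labels = model$labels,
                         stream_id = seq_len(M * p)),
                    class = "nm_layout")
  init <- sample_initial_conditions(model, laws, lay0, seed)
  sbar <- matrix(NA_real_, nsteps + 1L, p)
  y0_mean <- numeric(p)
  for (g in seq_len(p)) {
    idx <- which(init$pop == g)
    s0 <- sigmoid_eval(model$populations[[g]], init$V[idx])
    sbar[, g] <- mean(s0)
    y0_mean[g] <- mean(init$y[idx])
  }

  ybar_prev <- NULL
  residuals <- numeric(0)
  ybar_gap <- NA_real_
  for (it in seq_len(max_iter)) {
    ybar <- sbar
    for (g in seq_len(p)) {
      pop <- model$populations[[g]]
      ybar[, g] <- ybar_from_sbar(pop$a_r, pop$a_d, y0_mean[g],
                                  sbar[, g], times)
    }
    mf_in <- .paths_tibble(times, model$labels, sbar, ybar)
    ens <- simulate_limit_ensemble(model, mf_in, M = M, dt = dt, seed = seed,
                                   laws = laws, stride = max(1L, nsteps))
    sbar_new <- ens$sbar
    res_s <- max(abs(sbar_new - sbar))
    res_y <- if (is.null(ybar_prev)) Inf else max(abs(ybar - ybar_prev))
    residuals[it] <- if (is.null(ybar_prev)) res_s else max(res_s, res_y)
    ybar_gap <- max(abs(ens$ybar_emp - ybar))
    # iteration 1 only corrects the constant-in-time initial guess; declare
    # convergence from the first genuine fixed-point comparison onwards
    converged <- it >= 2L && residuals[it] < tol
    sbar <- damping * sbar_new + (1 - damping) * sbar
    ybar_prev <- ybar
    if (converged) {
      for (g in seq_len(p)) {
        pop <- model$populations[[g]]
        ybar[, g] <- ybar_from_sbar(pop$a_r, pop$a_d, y0_mean[g],
                                    sbar[, g], times)
      }
      out <- .paths_tibble(times, model$labels, sbar, ybar)
      class(out) <- c("nm_meanfield", class(out))
      attr(out, "iterations") <- it
      attr(out, "residuals") <- residuals
      attr(out, "ybar_gap") <- ybar_gap
      attr(out, "M") <- M
      attr(out, "dt") <- dt
      attr(out, "seed") <- seed
      return(out)
    }
  }
  abort(
    sprintf("Picard iteration did not reach tol = %g in %d iterations (last residual %g)",
            tol, max_iter, residuals[max_iter]),
    class = "mfneuron_picard_nonconvergence",
    residuals = residuals
  )
}

.paths_tibble <- function(times, labels, sbar, ybar) {
  bind_rows(lapply(seq_along(labels), function(g) {
    tibble(time = times, population = labels[g],
           sbar = sbar[, g], ybar = ybar[, g])
  }))
}

#' @method tidy nm_meanfield
#' @export
tidy.nm_meanfield <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "nm_meanfield")
  out
}

#' @method glance nm_meanfield
#' @export
glance.nm_meanfield <- function(x, ...) {
  r <- attr(x, "residuals")
  tibble(iterations = attr(x, "iterations"),
         final_residual = r[length(r)],
         ybar_gap = attr(x, "ybar_gap"),
         M = attr(x, "M"), dt = attr(x, "dt"), seed = attr(x, "seed"))
}

#' @method autoplot nm_meanfield
#' @export
autoplot.nm_meanfield <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), c("sbar", "ybar"),
                            names_to = "functional")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~functional, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}
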