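#' Check the boundary conditions for rectangular-cylinder invariance
#'
#' Verifies on grids, for every gating and synaptic coefficient pair of the
#' model, the two structural conditions under which a constrained coordinate
#' started in \[0, 1\] never leaves it: (i) the diffusion coefficient vanishes
#' for every `x` outside `(0, 1)`, and (ii) the drift is `>= 0` on
#' `x <= 0` and `<= 0` on `x >= 1`. Checks run per scalar constrained
#' coordinate, with all other coordinates (the potential) treated as the
#' environment; the grid deliberately extends beyond \[0, 1\] to exercise the
#' boundary clauses away from the endpoints.
#'
#' @param model an [model_spec()].
#' @param x_grid proportion grid covering at least `[-0.5, 1.5]`.
#' @param v_grid potential grid covering at least `[-100, 100]` mV.
#' @return a tibble with one row per (population, variable): `pass`, the two
#'   sub-flags `diffusion_vanishes` and `drift_sign`, the first violating grid
#'   point (if any), and a human-readable `detail`.
#' @export
check_boundary_conditions <- function(model,
                                      x_grid = seq(-0.5, 1.5, by = 0.005),
                                      v_grid = seq(-100, 100, by = 1)) {
  stopifnot(inherits(model, "nm_model"))
  if (min(x_grid) > -0.5 + 1e-9 || max(x_grid) < 1.5 - 1e-9) {
    abort("x_grid must cover [-0.5, 1.5]")
  }
  if (min(v_grid) > -100 + 1e-9 || max(v_grid) < 100 - 1e-9) {
    abort("v_grid must cover [-100, 100]")
  }
  out_x <- x_grid[x_grid <= 0 | x_grid >= 1]
  lo_x <- x_grid[x_grid <= 0]
  hi_x <- x_grid[x_grid >= 1]

  check_pair <- function(rho_v, zeta_v) {
    # rho_v, zeta_v: vectors over v_grid
    viol_diff <- NA_real_; viol_sign <- NA_real_
    chiv <- chi_eval(model$chi, out_x)
    # diffusion = sqrt(|rho(1-x) + zeta x|) * chi(x): vanishing off (0,1) is
    # decided by chi alone, but evaluate the product to certify it
    diff_ok <- TRUE
    if (any(chiv != 0)) {
      diff_ok <- FALSE
      viol_diff <- out_x[which(chiv != 0)[1]]
    }
    sign_ok <- TRUE
    for (x in lo_x) {
      drift <- rho_v * (1 - x) - zeta_v * x
      if (any(drift < 0)) { sign_ok <- FALSE; viol_sign <- x; break }
    }
    if (sign_ok) {
      for (x in hi_x) {
        drift <- rho_v * (1 - x) - zeta_v * x
        if (any(drift > 0)) { sign_ok <- FALSE; viol_sign <- x; break }
      }
    }
    list(diff_ok = diff_ok, sign_ok = sign_ok,
         viol_diff = viol_diff, viol_sign = viol_sign)
  }

  rows <- list()
  for (pop in model$populations) {
    vars <- c("y", if (pop$model_kind == "hh") c("n", "m", "h"))
    for (v in vars) {
      if (v == "y") {
        rho_v <- pop$a_r * sigmoid_eval(pop, v_grid)
        zeta_v <- rep(pop$a_d, length(v_grid))
      } else {
        rho_v <- pop$gates[[v]]$rho(v_grid)
        zeta_v <- pop$gates[[v]]$zeta(v_grid)
      }
      ck <- check_pair(rho_v, zeta_v)
      rows[[length(rows) + 1L]] <- tibble(
        population = pop$label, variable = v,
        diffusion_vanishes = ck$diff_ok, drift_sign = ck$sign_ok,
        pass = ck$diff_ok && ck$sign_ok,
        first_violation = if (!ck$diff_ok) ck$viol_diff else ck$viol_sign,
        detail = if (ck$diff_ok && ck$sign_ok) {
          "diffusion vanishes off (0,1); drift points inward at both boundaries"
        } else if (!ck$diff_ok) {
          sprintf("diffusion non-zero at x = %g", ck$viol_diff)
        } else {
          sprintf("drift sign condition violated at x = %g", ck$viol_sign)
        })
    }
  }
  bind_rows(rows)
}

#' Boundary-excursion bookkeeping for a simulated trajectory
#'
#' Pure bookkeeping over the stored samples of every proportion variable:
#' how many samples fell outside \[0, 1\], the maximum distance from the
#' interval, and the fraction of paths that stayed inside throughout. For
#' trajectories produced by [simulate_network()] the per-step accumulators
#' (which see every step, not only stored snapshots) are returned instead,
#' as they dominate the snapshot information.
#'
#' @param traj an `nm_trajectory` (from [simulate_network()]) or an
#'   `nm_ensemble` (from [simulate_limit_ensemble()]).
#' @return a tibble with one row per variable: `n_samples`, `n_outside`,
#'   `max_distance`, `n_paths`, `n_paths_inside`, `fraction_inside`.
#' @export
excursion_stats <- function(traj) {
  if (inherits(traj, "nm_ensemble")) traj <- traj$traj
  stopifnot(inherits(traj, "nm_trajectory"))
  if (is.null(traj$y) || length(traj$times) == 0L || ncol(traj$y) == 0L) {
    abort("empty trajectory")
  }
  if (!is.null(traj$excursions) && nrow(traj$excursions) > 0) {
    return(traj$excursions)
  }
  vars <- list(y = traj$y)
  if (!is.null(traj$n)) vars <- c(vars, list(n = traj$n, m = traj$m, h = traj$h))
  acc <- .exc_init(names(vars), ncol(traj$y))
  for (v in names(vars)) {
    mat <- vars[[v]]
    out <- mat < 0 | mat > 1
    a <- acc[[v]]
    a$n_samples <- length(mat)
    a$n_outside <- sum(out)
    a$max_dist <- if (any(out)) max(pmax(-mat, mat - 1)[out]) else 0
    a$inside <- colSums(out) == 0L
    acc[[v]] <- a
  }
  .exc_table(acc)
}

#' Simulate bare gating paths and record boundary excursions
#'
#' A focused experiment on the scalar gate equation
#' `dx = (rho (1 - x) - zeta x) dt + sqrt(|rho (1 - x) + zeta x|) chi(x) dW`
#' with constant bounded rates: `n_paths` independent Euler-Maruyama paths,
#' no clamping, with exact excursion accounting at every step. This is the
#' empirical form of the invariance statement: with a compliant envelope
#' `chi` and a small step, every path should stay in \[0, 1\]; with a
#' non-vanishing envelope (e.g. `chi_fun("constant")`) excursions appear with
#' positive frequency - the negative control.
#'
#' @param rho,zeta constant opening/closing rates (ms^-1, > 0).
#' @param chi a [chi_fun()] envelope.
#' @param x0 initial value in `[0, 1]` (all paths).
#' @param T,dt horizon and step (ms).
#' @param n_paths number of independent paths.
#' @param seed integer seed.
#' @return a one-row excursion tibble as in [excursion_stats()] (variable
#'   `"x"`), with attribute `final` holding the terminal values.
#' @export
run_gate_excursions <- function(rho, zeta, chi, x0 = 0.5, T = 10, dt = 1e-4,
                                n_paths = 200, seed = 1) {
  stopifnot(rho > 0, zeta > 0, inherits(chi, "nm_chi"),
            x0 >= 0, x0 <= 1, dt > 0)
  nsteps <- as.integer(round(T / dt))
  if (abs(T / dt - nsteps) > 1e-8) abort("T / dt must be an integer")
  x <- rep(x0, n_paths)
  sdt <- sqrt(dt)
  acc <- .exc_init("x", n_paths)
  acc <- .exc_update(acc, list(x = x))
  ids <- seq_len(n_paths)
  step <- 0L; chunk <- 0L
  while (step < nsteps) {
    len <- min(.CHUNK_STEPS, nsteps - step)
    z <- .gen_chunk(seed, ids, .CH[["n"]], chunk, len)
    for (k in seq_len(len)) {
      drift <- rho * (1 - x) - zeta * x
      diffu <- sqrt(abs(rho * (1 - x) + zeta * x)) * chi_eval(chi, x)
      x <- x + drift * dt + diffu * (sdt * z[k, ])
      acc <- .exc_update(acc, list(x = x))
    }
    step <- step + len; chunk <- chunk + 1L
    if (!all(is.finite(x))) {
      abort(sprintf("non-finite gate value in path %d at step %d",
                    which(!is.finite(x))[1], step))
    }
  }
  out <- .exc_table(acc)
  attr(out, "final") <- x
  out
}
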