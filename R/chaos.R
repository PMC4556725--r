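# Coupled particle/limit construction: the N-neuron system and N independent
# mean-field copies are driven by the same Brownian increments and started
# from the same initial draws; in the sign-preserving model the copies reuse
# the network's conductance paths (J-tilde == J exactly). The pathwise
# distance between the two systems measures the finite-N error.

.run_coupled <- function(model, pop_idx, stream_id, group, init, nsteps, dt,
                         seed, ybar_path, track_idx, stride = 1L,
                         store = FALSE) {
  par <- .sys_params(model, pop_idx, group)
  n <- par$n; p <- par$p
  sdt <- sqrt(dt)
  ms <- .mean_structure(pop_idx, stream_id, group, p)
  G <- nrow(track_idx)
  flat <- as.vector(track_idx)

  pick <- c("V", "y", "w", "gn", "gm", "gh", "J")
  st_n <- init[pick]
  st_l <- init[pick]
  supvec <- numeric(G)  # identical at t = 0

  snap_n <- snap_l <- NULL
  if (store) {
    nsnap <- nsteps %/% stride + 1L
    mk <- function() {
      s <- list(V = matrix(NA_real_, nsnap, n), y = matrix(NA_real_, nsnap, n),
                w = matrix(NA_real_, nsnap, n))
      if (par$any_hh) {
        s$gn <- matrix(NA_real_, nsnap, n); s$gm <- matrix(NA_real_, nsnap, n)
        s$gh <- matrix(NA_real_, nsnap, n)
      }
      if (!is.null(init$J)) s$J <- array(NA_real_, c(nsnap, n, p))
      s
    }
    snap_n <- mk(); snap_l <- mk()
    put <- function(s, row, st) {
      s$V[row, ] <- st$V; s$y[row, ] <- st$y; s$w[row, ] <- st$w
      if (par$any_hh) { s$gn[row, ] <- st$gn; s$gm[row, ] <- st$gm; s$gh[row, ] <- st$gh }
      if (!is.null(st$J)) s$J[row, , ] <- st$J
      s
    }
    snap_n <- put(snap_n, 1L, st_n); snap_l <- put(snap_l, 1L, st_l)
  }

  sqdiff <- function(a, b) {
    d <- (a$V[flat] - b$V[flat])^2 + (a$y[flat] - b$y[flat])^2 +
      (a$w[flat] - b$w[flat])^2
    if (par$any_hh) {
      d <- d + (a$gn[flat] - b$gn[flat])^2 + (a$gm[flat] - b$gm[flat])^2 +
        (a$gh[flat] - b$gh[flat])^2
    }
    # the conductance block contributes exactly zero: J-tilde == J by coupling
    rowSums(matrix(d, nrow = G))
  }

  step <- 0L; chunk <- 0L
  while (step < nsteps) {
    len <- min(.CHUNK_STEPS, nsteps - step)
    chm <- .chunk_increments(seed, stream_id, par, chunk, len, NULL)
    for (k in seq_len(len)) {
      gstep <- step + k
      dW <- .dW_at(chm, k, par, n)
      ybar_net <- .empirical_ybar(st_n$y, ms, group, n, p)
      ybar_lim <- matrix(ybar_path[gstep, ], nrow = n, ncol = p, byrow = TRUE)
      st_n <- .system_step(st_n, par, dt, sdt, dW, ybar_net)
      st_l <- .system_step(st_l, par, dt, sdt, dW, ybar_lim)
      if (!is.null(st_n$J)) st_l$J <- st_n$J  # shared CIR paths (equal anyway)
      supvec <- pmax(supvec, sqdiff(st_n, st_l))
      if (store && gstep %% stride == 0L) {
        row <- gstep %/% stride + 1L
        snap_n <- put(snap_n, row, st_n); snap_l <- put(snap_l, row, st_l)
      }
    }
    step <- step + len; chunk <- chunk + 1L
    .check_finite(st_n, step); .check_finite(st_l, step)
  }
  list(supvec = supvec, snap_n = snap_n, snap_l = snap_l,
       final_n = st_n, final_l = st_l, par = par)
}

#' Simulate the coupled network / mean-field pair
#'
#' Advances the N-neuron system and N independent mean-field limit copies
#' (one per neuron, of that neuron's population) in lockstep: identical
#' Gaussian increments per (neuron, channel), identical initial draws, and -
#' in the sign-preserving model - identical conductance sample paths. The
#' network uses its empirical population means of `y`; the copies use the
#' deterministic `ybar` from `meanfield`. At `t = 0` the two systems coincide
#' exactly; their subsequent pathwise distance is the finite-N coupling error.
#'
#' @param model an [model_spec()].
#' @param layout an [population_layout()].
#' @param meanfield mean-field paths (`time`, `population`, `ybar`), typically
#'   from [picard_solve()], on the simulation grid.
#' @param T,dt horizon and step (ms); the `meanfield` grid must match.
#' @param seed integer seed (drives initial draws and shared increments).
#' @param laws an [init_law_spec()].
#' @param stride snapshot stride for the stored trajectories.
#' @return an object of class `nm_coupling` holding the two trajectories
#'   (`network`, `limit`), the per-replicate running supremum, and provenance.
#' @export
simulate_coupled <- function(model, layout, meanfield, T, dt, seed,
                             laws = NULL, stride = 1L) {
  stopifnot(inherits(model, "nm_model"), inherits(layout, "nm_layout"))
  nsteps <- T / dt
  if (abs(nsteps - round(nsteps)) > 1e-8) abort("T / dt must be an integer")
  nsteps <- as.integer(round(nsteps))
  mf <- .meanfield_matrix(meanfield, model$labels, "ybar", nsteps + 1L)
  if (max(abs(diff(mf$times) - dt)) > 1e-9) {
    abort("mean-field grid spacing does not equal dt")
  }
  init <- sample_initial_conditions(model, laws, layout, seed)
  track_idx <- matrix(vapply(seq_len(model$p_bar),
                             function(g) which(layout$assignment == g)[1],
                             integer(1)), nrow = 1L)
  res <- .run_coupled(model, layout$assignment, layout$stream_id,
                      rep(1L, layout$N), init, nsteps, dt, seed, mf$m,
                      track_idx, stride = as.integer(stride), store = TRUE)
  times <- seq(0, nsteps, by = stride) * dt
  wrap <- function(snap, final) {
    .new_trajectory(list(par = res$par, snap = snap, final = final,
                         exc = tibble()),
                    model, times, seed, dt, stride, layout$stream_id)
  }
  structure(
    list(network = wrap(res$snap_n, res$final_n),
         limit = wrap(res$snap_l, res$final_l),
         sup_tracked = res$supvec, track_idx = track_idx,
         meanfield = meanfield, layout = layout,
         provenance = list(seed = seed, dt = dt, T = T)),
    class = "nm_coupling"
  )
}

#' @export
print.nm_coupling <- function(x, ...) {
  cat(sprintf("<nm_coupling> N = %d, T = %g ms, sup-square deviation %.4g (tracked index set)\n",
              x$layout$N, x$provenance$T, x$sup_tracked[1]))
  invisible(x)
}

#' Pathwise coupling error over the stored grid
#'
#' The supremum over stored snapshot times of the summed squared state
#' deviation `sum over populations alpha of |R^{i_alpha, N}_t -
#' R-tilde^{i_alpha}_t|^2`, for an index set containing exactly one neuron per
#' population. The state norm sums every lumped component (potential,
#' conductance block, synaptic, recovery and gating variables); the
#' conductance block contributes zero by construction of the coupling.
#'
#' @param run an [simulate_coupled()] result.
#' @param indices integer vector with exactly one neuron index per population,
#'   in population order.
#' @return the sup-square deviation (a scalar `>= 0`).
#' @export
coupling_error <- function(run, indices) {
  stopifnot(inherits(run, "nm_coupling"))
  p <- length(run$layout$labels)
  if (length(indices) != p ||
      !identical(as.integer(run$layout$assignment[indices]), seq_len(p))) {
    abort("`indices` must contain exactly one neuron of each population, in population order")
  }
  a <- run$network; b <- run$limit
  d <- (a$V[, indices, drop = FALSE] - b$V[, indices, drop = FALSE])^2 +
    (a$y[, indices, drop = FALSE] - b$y[, indices, drop = FALSE])^2 +
    (a$w[, indices, drop = FALSE] - b$w[, indices, drop = FALSE])^2
  if (!is.null(a$n)) {
    d <- d + (a$n[, indices, drop = FALSE] - b$n[, indices, drop = FALSE])^2 +
      (a$m[, indices, drop = FALSE] - b$m[, indices, drop = FALSE])^2 +
      (a$h[, indices, drop = FALSE] - b$h[, indices, drop = FALSE])^2
  }
  if (!is.null(a$J)) {
    for (g in seq_len(p)) {
      ja <- a$J[, indices, g, drop = FALSE]; dim(ja) <- dim(ja)[1:2]
      jb <- b$J[, indices, g, drop = FALSE]; dim(jb) <- dim(jb)[1:2]
      d <- d + (ja - jb)^2
    }
  }
  max(rowSums(d))
}

#' Scan the propagation-of-chaos error over network sizes
#'
#' For each `N` in `N_list`, runs `replications` independent coupled
#' simulations ([simulate_coupled()] semantics, batched for speed), measures
#' the per-replication sup-square deviation at one neuron per population, and
#' reports the estimate `D_hat_N` (mean over replications) with its standard
#' error, the theory-normalised `sqrt(N) * D_hat_N` (the quantity bounded by a
#' constant in the mean-field analysis), and the least-squares slope of
#' `log D_hat_N` against `log N` with a nonparametric bootstrap confidence
#' interval. The slope is expected between roughly -1 (globally Lipschitz
#' interaction rate, 1/N) and -0.5 (the proven 1/sqrt(N) bound).
#'
#' One mean-field solve (accuracy `M_meanfield`, default 10x the largest `N`)
#' is shared across the whole scan; its Monte-Carlo quality is reported
#' alongside so that the bias floor is visible.
#'
#' @param model an [model_spec()] (the sign-preserving model is the reference
#'   configuration; the simple model works identically).
#' @param N_list increasing network sizes, each compatible with the model's
#'   proportions.
#' @param replications independent replications per N (fresh initial draws and
#'   noise streams).
#' @param T,dt horizon and step (ms).
#' @param base_seed integer master seed.
#' @param laws an [init_law_spec()].
#' @param meanfield optionally a precomputed [picard_solve()] result on the
#'   same grid.
#' @param M_meanfield Monte-Carlo copies for the shared mean-field solve.
#' @param tol Picard tolerance for the mean-field solve.
#' @param bootstrap bootstrap resamples for the slope confidence interval.
#' @return an object of class `nm_chaos_scan`: a tibble `(N, D_hat, se,
#'   sqrtN_D)` with attributes `slope`, `slope_ci`, `replications`, `per_rep`
#'   (the raw per-replication deviations), and the mean-field provenance.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
chaos_scan <- function(model, N_list, replications = 32, T = 5, dt = 1e-3,
                       base_seed = 1, laws = NULL, meanfield = NULL,
                       M_meanfield = NULL, tol = 1e-3, bootstrap = 1000) {
  stopifnot(inherits(model, "nm_model"), length(N_list) >= 1,
            !is.unsorted(N_list))
  nsteps <- as.integer(round(T / dt))
  layouts <- lapply(N_list, function(N) population_layout(model, N))
  if (is.null(laws)) laws <- init_law_spec(model)
  if (is.null(meanfield)) {
    if (is.null(M_meanfield)) M_meanfield <- 10L * max(N_list)
    meanfield <- picard_solve(model, T = T, dt = dt, M = M_meanfield,
                              tol = tol, max_iter = 12,
                              seed = .mix_seed(base_seed, 0L, 42L, 0L),
                              laws = laws)
  }
  mf <- .meanfield_matrix(meanfield, model$labels, "ybar", nsteps + 1L)
  p <- model$p_bar
  reps <- as.integer(replications)

  per_rep <- matrix(NA_real_, nrow = reps, ncol = length(N_list),
                    dimnames = list(NULL, paste0("N", N_list)))
  for (ni in seq_along(N_list)) {
    N <- N_list[ni]
    lay <- layouts[[ni]]
    pop_idx <- rep(lay$assignment, reps)
    group <- rep(seq_len(reps), each = N)
    stream_id <- seq_len(N * reps)
    biglay <- structure(list(assignment = pop_idx,
                             counts = lay$counts * reps,
                             N = as.integer(N * reps), labels = model$labels,
                             stream_id = stream_id),
                        class = "nm_layout")
    seed_N <- .mix_seed(base_seed, N, 7L, 0L)
    init <- sample_initial_conditions(model, laws, biglay, seed_N)
    track_idx <- matrix(0L, nrow = reps, ncol = p)
    for (g in seq_len(p)) {
      first_g <- which(lay$assignment == g)[1]
      track_idx[, g] <- (seq_len(reps) - 1L) * N + first_g
    }
    res <- .run_coupled(model, pop_idx, stream_id, group, init, nsteps, dt,
                        seed_N, mf$m, track_idx, store = FALSE)
    per_rep[, ni] <- res$supvec
  }

  D_hat <- unname(colMeans(per_rep))
  se <- unname(apply(per_rep, 2, sd)) / sqrt(reps)
  out <- tibble(N = as.integer(N_list), D_hat = D_hat, se = se,
                sqrtN_D = sqrt(N_list) * D_hat)

  slope <- NA_real_; slope_ci <- c(NA_real_, NA_real_)
  if (length(N_list) >= 2 && all(D_hat > 0)) {
    lx <- log(N_list)
    slope <- unname(coef(lm(log(D_hat) ~ lx))[2])
    if (bootstrap > 0) {
      bs <- vapply(seq_len(bootstrap), function(b) {
        Db <- vapply(seq_along(N_list), function(ni) {
          mean(per_rep[sample.int(reps, reps, replace = TRUE), ni])
        }, numeric(1))
        if (any(Db <= 0)) return(NA_real_)
        unname(coef(lm(log(Db) ~ lx))[2])
      }, numeric(1))
      slope_ci <- unname(quantile(bs, c(0.025, 0.975), na.rm = TRUE))
    }
  }
  class(out) <- c("nm_chaos_scan", class(out))
  attr(out, "slope") <- slope
  attr(out, "slope_ci") <- slope_ci
  attr(out, "replications") <- reps
  attr(out, "per_rep") <- per_rep
  attr(out, "meanfield_info") <- if (inherits(meanfield, "nm_meanfield")) {
    as.list(glance(meanfield))
  } else {
    list()
  }
  attr(out, "T") <- T
  attr(out, "dt") <- dt
  attr(out, "base_seed") <- base_seed
  out
}

#' @method tidy nm_chaos_scan
#' @export
tidy.nm_chaos_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "nm_chaos_scan")
  out
}

#' @method glance nm_chaos_scan
#' @export
glance.nm_chaos_scan <- function(x, ...) {
  ci <- attr(x, "slope_ci")
  tibble(slope = attr(x, "slope"),
         slope_ci_low = ci[1], slope_ci_high = ci[2],
         replications = attr(x, "replications"),
         sqrtN_D_ratio = if (all(x$D_hat > 0)) {
           max(x$sqrtN_D) / min(x$sqrtN_D)
         } else {
           NA_real_
         },
         T = attr(x, "T"), dt = attr(x, "dt"))
}

#' @method autoplot nm_chaos_scan
#' @export
autoplot.nm_chaos_scan <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$N, y = .data$D_hat)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$D_hat - 2 * .data$se,
                                          ymax = .data$D_hat + 2 * .data$se)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "N (log)", y = expression(hat(D)[N] ~ "(log)"),
                  subtitle = sprintf("fitted log-log slope %.2f",
                                     attr(object, "slope"))) +
    ggplot2::theme_minimal()
}
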