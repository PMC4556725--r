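# Internal simulation engine.
#
# Noise layout: counter-based streams. Every particle owns one stream per
# channel (V, y, n, m, h, one B per target population, plus an "init" channel
# for its initial draw), identified by (seed, stream id, channel, chunk).
# Increments are generated in fixed-size chunks so that the value of increment
# k of a stream depends only on (seed, stream id, channel, k) - never on which
# other streams exist or on how the simulation is batched. This is what makes
# couplings (shared streams), permutation tests (re-mapped stream ids) and
# replicate batching exact.

.CHUNK_STEPS <- 2048L

.CH <- c(V = 1L, y = 2L, n = 3L, m = 4L, h = 5L, init = 6L)
.ch_B <- function(gamma_index) 10L + gamma_index

# Mix (seed, id, channel, chunk) into a 32-bit seed. Multiplier small enough
# that products stay exact in doubles (69061 * 2^31 < 2^53).
.mix_seed <- function(seed, id, channel, chunk) {
  P <- 2147483647
  h <- seed %% P
  h <- (h * 69061 + id) %% P
  h <- (h * 69061 + channel * 7919) %% P
  h <- (h * 69061 + chunk) %% P
  as.integer(h)
}

# standard-normal increments for steps [chunk*CHUNK + 1, ...], one column per id
.gen_chunk <- function(seed, ids, channel, chunk, len) {
  out <- matrix(0, nrow = len, ncol = length(ids))
  for (j in seq_along(ids)) {
    set.seed(.mix_seed(seed, ids[j], channel, chunk))
    out[, j] <- rnorm(len)
  }
  out
}

# ---- per-particle parameter expansion ---------------------------------------

.sys_params <- function(model, pop_idx, group = NULL) {
  n <- length(pop_idx)
  p <- model$p_bar
  pops <- model$populations
  if (is.null(group)) group <- rep(1L, n)

  gpar <- function(f) vapply(pops, f, numeric(1))[pop_idx]
  kind <- vapply(pops, function(x) x$model_kind, "")[pop_idx]
  is_hh <- kind == "hh"

  par <- list(
    n = n, p = p, labels = model$labels, pop_idx = pop_idx, group = group,
    n_groups = max(group),
    conductance_model = model$conductance_model,
    chi = model$chi,
    any_hh = any(is_hh), is_hh = is_hh, mask_fhn = as.numeric(!is_hh),
    sigma_V = gpar(function(x) x$sigma_V),
    a_r = gpar(function(x) x$a_r),
    a_d = gpar(function(x) x$a_d),
    sg_C = gpar(function(x) x$sigmoid$C),
    sg_l = gpar(function(x) x$sigmoid$lambda),
    sg_d = gpar(function(x) x$sigmoid$delta),
    fhn_a = gpar(function(x) if (is.null(x$fhn)) 0 else x$fhn$a),
    fhn_b = gpar(function(x) if (is.null(x$fhn)) 0 else x$fhn$b),
    fhn_c = gpar(function(x) if (is.null(x$fhn)) 0 else x$fhn$c)
  )

  # HH populations: per-population particle index sets + rate closures
  par$hh_pops <- list()
  for (ai in seq_len(p)) {
    pop <- pops[[ai]]
    if (pop$model_kind == "hh") {
      idx <- which(pop_idx == ai)
      if (length(idx)) {
        par$hh_pops[[length(par$hh_pops) + 1L]] <-
          list(idx = idx, gates = pop$gates, hh = pop$hh)
      }
    }
  }

  # interaction parameters as n x p matrices (row = particle, col = target pop)
  inter <- model$interactions
  key <- matrix(0, nrow = p, ncol = p)  # [alpha, gamma] -> row of inter
  for (r in seq_len(nrow(inter))) {
    key[match(inter$from[r], model$labels), match(inter$to[r], model$labels)] <- r
  }
  pick <- function(col) {
    m <- matrix(0, nrow = n, ncol = p)
    for (g in seq_len(p)) m[, g] <- inter[[col]][key[pop_idx, g]]
    m
  }
  par$V_rev_m  <- pick("V_rev")
  par$Jbar_m   <- pick("J_bar")
  par$sigmaJ_m <- pick("sigma_J")
  par$theta_m  <- if (model$conductance_model == "sign_preserving") {
    pick("theta")
  } else {
    matrix(0, n, p)
  }
  par
}

# presynaptic population means in canonical (stream-id sorted) order, so that
# summation order - and hence the floating-point result - is invariant under
# any permutation of particle storage positions.
.mean_structure <- function(pop_idx, stream_id, group, p) {
  G <- max(group)
  lapply(seq_len(p), function(g) {
    idx <- which(pop_idx == g)
    idx <- idx[order(stream_id[idx])]
    grp <- group[idx]
    gl <- sort(unique(grp))
    list(idx = idx, grp = grp, gl = gl, G = G,
         count_gl = as.numeric(tabulate(grp, nbins = G)[gl]))
  })
}

.empirical_ybar <- function(y, ms, group, n, p) {
  out <- matrix(0, nrow = n, ncol = p)
  for (g in seq_len(p)) {
    s <- ms[[g]]
    if (!length(s$idx)) next
    per_group <- numeric(s$G)
    tot <- rowsum(y[s$idx], s$grp, reorder = TRUE)[, 1]  # ordered by s$gl
    per_group[s$gl] <- tot / s$count_gl
    out[, g] <- per_group[group]
  }
  out
}

.sigmoid_vec <- function(par, V) {
  par$sg_C / (1 + exp(-par$sg_l * (V - par$sg_d)))
}

# membrane drift F_alpha(V, q) for all particles (mixed kinds)
.membrane_F <- function(par, V, w, gn, gm, gh) {
  F <- par$mask_fhn * (-V^3 / 3 + V - w)
  for (pp in par$hh_pops) {
    i <- pp$idx; hh <- pp$hh; vi <- V[i]
    F[i] <- (-hh$g_Na * gm[i]^3 * gh[i] * (vi - hh$E_Na) -
               hh$g_K * gn[i]^4 * (vi - hh$E_K) -
               hh$g_L * (vi - hh$E_L) + hh$I_app) / hh$C_m
  }
  F
}

# One Euler-Maruyama step of a particle system. `dW` holds standard-normal
# increments (list: V, y, n, m, h vectors; B an n x p matrix); `ybar_eff` is
# the n x p matrix of presynaptic means seen by each particle (empirical for
# the network, E[y] for mean-field copies). All coefficients are evaluated at
# the pre-step state.
.system_step <- function(st, par, dt, sdt, dW, ybar_eff, clamp = FALSE) {
  V <- st$V; y <- st$y; w <- st$w
  gn <- st$gn; gm <- st$gm; gh <- st$gh; J <- st$J

  F <- .membrane_F(par, V, w, gn, gm, gh)
  dvint <- V - par$V_rev_m
  if (par$conductance_model == "sign_preserving") {
    int_drift <- rowSums(dvint * J * ybar_eff)
    V_new <- V + (F - int_drift) * dt + par$sigma_V * (sdt * dW$V)
    J_new <- cir_step(J, par$theta_m, par$Jbar_m, par$sigmaJ_m, dt, sdt * dW$B)
  } else {
    int_drift <- rowSums(dvint * par$Jbar_m * ybar_eff)
    int_diff  <- rowSums(dvint * par$sigmaJ_m * ybar_eff * (sdt * dW$B))
    V_new <- V + (F - int_drift) * dt - int_diff + par$sigma_V * (sdt * dW$V)
    J_new <- NULL
  }

  s <- .sigmoid_vec(par, V)
  open_y <- par$a_r * s
  ydrift <- open_y * (1 - y) - par$a_d * y
  ydiff  <- sqrt(abs(open_y * (1 - y) + par$a_d * y)) * chi_eval(par$chi, y)
  y_new  <- y + ydrift * dt + ydiff * (sdt * dW$y)

  w_new <- w + par$fhn_c * (V + par$fhn_a - par$fhn_b * w) * dt

  gn_new <- gn; gm_new <- gm; gh_new <- gh
  for (pp in par$hh_pops) {
    i <- pp$idx; vi <- V[i]
    for (gname in c("n", "m", "h")) {
      rf <- pp$gates[[gname]]
      rho <- rf$rho(vi); zeta <- rf$zeta(vi)
      x <- switch(gname, n = gn[i], m = gm[i], h = gh[i])
      drift <- rho * (1 - x) - zeta * x
      diffu <- sqrt(abs(rho * (1 - x) + zeta * x)) * chi_eval(par$chi, x)
      x2 <- x + drift * dt + diffu * (sdt * dW[[gname]][i])
      switch(gname, n = gn_new[i] <- x2, m = gm_new[i] <- x2,
             h = gh_new[i] <- x2)
    }
  }

  if (clamp) {
    y_new <- pmin(pmax(y_new, 0), 1)
    if (par$any_hh) {
      gn_new <- pmin(pmax(gn_new, 0), 1)
      gm_new <- pmin(pmax(gm_new, 0), 1)
      gh_new <- pmin(pmax(gh_new, 0), 1)
    }
  }

  list(V = V_new, y = y_new, w = w_new,
       gn = gn_new, gm = gm_new, gh = gh_new, J = J_new)
}

.state_channels <- function(par) {
  ch <- c("V", "y")
  if (par$any_hh) ch <- c(ch, "n", "m", "h")
  ch
}

# fetch one chunk of standard-normal increments for every needed channel
.chunk_increments <- function(seed, stream_id, par, chunk, len, increments) {
  if (!is.null(increments)) {
    # caller-supplied full increment arrays (advanced use: shared-noise
    # dt-refinement studies); slice the rows of this chunk
    rows <- (chunk * .CHUNK_STEPS + 1L):(chunk * .CHUNK_STEPS + len)
    out <- list(V = increments$V[rows, , drop = FALSE],
                y = increments$y[rows, , drop = FALSE])
    for (g in c("n", "m", "h")) {
      if (!is.null(increments[[g]])) out[[g]] <- increments[[g]][rows, , drop = FALSE]
    }
    out$B <- lapply(increments$B, function(mB) mB[rows, , drop = FALSE])
    return(out)
  }
  out <- list(V = .gen_chunk(seed, stream_id, .CH[["V"]], chunk, len),
              y = .gen_chunk(seed, stream_id, .CH[["y"]], chunk, len))
  if (par$any_hh) {
    for (g in c("n", "m", "h")) {
      out[[g]] <- .gen_chunk(seed, stream_id, .CH[[g]], chunk, len)
    }
  }
  out$B <- lapply(seq_len(par$p), function(g) {
    .gen_chunk(seed, stream_id, .ch_B(g), chunk, len)
  })
  out
}

.dW_at <- function(chm, k, par, n) {
  dW <- list(V = chm$V[k, ], y = chm$y[k, ])
  if (par$any_hh) {
    dW$n <- chm$n[k, ]; dW$m <- chm$m[k, ]; dW$h <- chm$h[k, ]
  } else {
    dW$n <- dW$m <- dW$h <- NULL
  }
  dW$B <- matrix(vapply(chm$B, function(mB) mB[k, ], numeric(n)),
                 nrow = n, ncol = par$p)
  dW
}

.check_finite <- function(st, step) {
  for (nm2 in c("V", "y", "w", "gn", "gm", "gh", "J")) {
    v <- st[[nm2]]
    if (!is.null(v) && !all(is.finite(v))) {
      bad <- which(!is.finite(v))[1]
      neuron <- if (is.matrix(v)) ((bad - 1L) %% nrow(v)) + 1L else bad
      abort(sprintf(
        "non-finite value in component '%s' of neuron %d at step %d",
        nm2, neuron, step))
    }
  }
}

# excursion accumulators for the proportion variables
.exc_init <- function(vars, n) {
  setNames(lapply(vars, function(v) {
    list(n_outside = 0, max_dist = 0, inside = rep(TRUE, n), n_samples = 0)
  }), vars)
}

.exc_update <- function(acc, vals) {
  for (v in names(vals)) {
    x <- vals[[v]]
    a <- acc[[v]]
    a$n_samples <- a$n_samples + length(x)
    out <- x < 0 | x > 1
    if (any(out)) {
      a$n_outside <- a$n_outside + sum(out)
      a$max_dist <- max(a$max_dist, max(pmax(-x, x - 1)[out]))
      a$inside <- a$inside & !out
    }
    acc[[v]] <- a
  }
  acc
}

.exc_table <- function(acc) {
  bind_rows(lapply(names(acc), function(v) {
    a <- acc[[v]]
    tibble(variable = v,
           n_samples = a$n_samples,
           n_outside = a$n_outside,
           max_distance = a$max_dist,
           n_paths = length(a$inside),
           n_paths_inside = sum(a$inside),
           fraction_inside = mean(a$inside))
  }))
}
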