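#' Define one neuron population
#'
#' A population is a set of exchangeable neurons sharing a membrane model
#' (FitzHugh-Nagumo or Hodgkin-Huxley), a membrane noise level, synaptic
#' kinetics, and a sigmoidal release function. Units are mV and ms throughout;
#' all rates are in ms^-1.
#'
#' @param label population identifier (a string).
#' @param model_kind `"fhn"` (cubic membrane drift with a linear recovery
#'   variable `w`) or `"hh"` (classic ionic-current drift with gating
#'   variables `n`, `m`, `h`).
#' @param sigma_V membrane noise intensity (mV ms^-1/2, >= 0).
#' @param a_r,a_d synaptic rise and decay rates (ms^-1, > 0).
#' @param sigmoid list `(C, lambda, delta)` of the release sigmoid
#'   `S(v) = C / (1 + exp(-lambda (v - delta)))`; `C` is the maximal
#'   transmitter concentration, `lambda` the steepness (mV^-1), `delta` the
#'   half-activation potential (mV).
#' @param fhn list `(a, b, c)` of recovery parameters (FHN only):
#'   `dw = c (V + a - b w) dt`.
#' @param hh list of membrane parameters (HH only): maximal conductances
#'   `g_Na`, `g_K`, `g_L` (mS cm^-2), reversals `E_Na`, `E_K`, `E_L` (mV),
#'   capacitance `C_m` (uF cm^-2), applied current `I_app` (uA cm^-2).
#' @param v_clip interval to which the potential is clipped before gating
#'   rates are evaluated (makes the rates bounded Lipschitz).
#' @param floor_rate lower floor nu on every gating rate (ms^-1), the
#'   coercivity constant.
#' @return an object of class `nm_population`.
#' @seealso [model_spec()], [fhn_population()], [hh_population()]
#' @export
population_spec <- function(label, model_kind = c("fhn", "hh"),
                            sigma_V = 0.2, a_r = 1.0, a_d = 0.3,
                            sigmoid = list(C = 1, lambda = 1, delta = 0),
                            fhn = NULL, hh = NULL,
                            v_clip = c(-100, 100), floor_rate = 1e-3) {
  model_kind <- match.arg(model_kind)
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    abort("`label` must be a non-empty string")
  }
  if (sigma_V < 0) abort(sprintf("population '%s': sigma_V must be >= 0", label))
  if (a_r <= 0 || a_d <= 0) {
    abort(sprintf("population '%s': a_r and a_d must be > 0", label))
  }
  sg <- sigmoid
  if (is.null(sg$C) || is.null(sg$lambda) || is.null(sg$delta) ||
      sg$C <= 0 || sg$lambda <= 0) {
    abort(sprintf("population '%s': sigmoid needs C > 0, lambda > 0, delta", label))
  }
  if (model_kind == "fhn") {
    if (is.null(fhn)) fhn <- list(a = 0.7, b = 0.8, c = 0.08)
    if (any(!c("a", "b", "c") %in% names(fhn))) {
      abort(sprintf("population '%s': fhn needs fields a, b, c", label))
    }
    gates <- NULL
  } else {
    if (is.null(hh)) {
      hh <- list(g_Na = 120, E_Na = 50, g_K = 36, E_K = -77,
                 g_L = 0.3, E_L = -54.387, C_m = 1, I_app = 0)
    }
    need <- c("g_Na", "E_Na", "g_K", "E_K", "g_L", "E_L", "C_m", "I_app")
    if (any(!need %in% names(hh))) {
      abort(sprintf("population '%s': hh needs fields %s", label,
                    paste(setdiff(need, names(hh)), collapse = ", ")))
    }
    if (hh$C_m <= 0) abort(sprintf("population '%s': C_m must be > 0", label))
    gates <- .hh_rate_funs(v_clip, floor_rate)
  }
  structure(
    list(label = label, model_kind = model_kind, sigma_V = sigma_V,
         a_r = a_r, a_d = a_d, sigmoid = sg, fhn = fhn, hh = hh,
         gates = gates, v_clip = v_clip, floor_rate = floor_rate),
    class = "nm_population"
  )
}

#' @rdname population_spec
#' @param ... passed on to [population_spec()].
#' @export
fhn_population <- function(label = "exc", ...) {
  population_spec(label, model_kind = "fhn", ...)
}

#' @rdname population_spec
#' @export
hh_population <- function(label = "exc", ...) {
  population_spec(label, model_kind = "hh", sigma_V = 1.0,
                  sigmoid = list(C = 1, lambda = 0.2, delta = -30), ...)
}

#' Define the synaptic interaction table
#'
#' One row per ordered pair (post, pre) of populations: the postsynaptic
#' population `from` receives input from presynaptic population `to` with
#' reversal potential `V_rev` (mV), mean maximal conductance `J_bar` (>= 0),
#' conductance noise `sigma_J` (>= 0) and, for the sign-preserving
#' (Cox-Ingersoll-Ross) conductance model, reversion rate `theta` (ms^-1, > 0).
#'
#' @param from,to population labels (postsynaptic, presynaptic).
#' @param V_rev synaptic reversal potential (mV).
#' @param J_bar mean maximal conductance (>= 0).
#' @param sigma_J conductance noise intensity (>= 0).
#' @param theta CIR reversion rate (> 0); required by the sign-preserving
#'   model, must be absent (`NA`) in the simple model.
#' @return a one-row tibble; bind rows to build the full table.
#' @export
interaction_spec <- function(from, to, V_rev = 0, J_bar = 0.5,
                             sigma_J = 0.2, theta = NA_real_) {
  tibble(from = from, to = to, V_rev = V_rev, J_bar = J_bar,
         sigma_J = sigma_J, theta = theta)
}

#' Assemble a full model specification
#'
#' Bundles populations, the interaction table, the noise envelope chi, the
#' population proportions, and the conductance model into a validated object.
#' The two conductance models are:
#' \describe{
#'   \item{`"simple"`}{the maximal conductance fluctuates around its mean as
#'     white noise; the interaction enters the membrane equation through both
#'     a drift and a diffusion term scaled by the population mean of `y`.}
#'   \item{`"sign_preserving"`}{each neuron carries one CIR conductance process
#'     per target population,
#'     `dJ = theta (J_bar - J) dt + sigma_J sqrt(J) dB`, guaranteeing J >= 0.}
#' }
#'
#' @param populations a list of [population_spec()] objects.
#' @param interactions a data frame with columns `from`, `to`, `V_rev`,
#'   `J_bar`, `sigma_J`, `theta` (see [interaction_spec()]). Missing ordered
#'   pairs are filled with zero coupling.
#' @param chi a [chi_fun()] envelope.
#' @param proportions named numeric vector of population proportions
#'   `c_gamma` (positive, summing to 1). Default: equal proportions.
#' @param conductance_model `"sign_preserving"` (default) or `"simple"`.
#' @return an object of class `nm_model`, with derived fields `p_bar` (number
#'   of populations) and `ell = p_bar^2 + 6 p_bar` (the lumped state
#'   dimension: per population V, p_bar conductances, y, w, n, m, h).
#' @examples
#' m <- fhn_model_spec()
#' m$ell
#' @export
model_spec <- function(populations, interactions = NULL, chi = chi_fun(),
                       proportions = NULL,
                       conductance_model = c("sign_preserving", "simple")) {
  conductance_model <- match.arg(conductance_model)
  if (inherits(populations, "nm_population")) populations <- list(populations)
  stopifnot(length(populations) >= 1L,
            all(vapply(populations, inherits, TRUE, "nm_population")))
  labels <- vapply(populations, `[[`, "", "label")
  if (anyDuplicated(labels)) abort("duplicated population labels")
  p_bar <- length(labels)

  if (is.null(proportions)) {
    proportions <- setNames(rep(1 / p_bar, p_bar), labels)
  }
  if (is.null(names(proportions)) || !setequal(names(proportions), labels)) {
    abort("`proportions` must be named by the population labels")
  }
  proportions <- proportions[labels]
  if (any(proportions <= 0) || abs(sum(proportions) - 1) > 1e-12) {
    abort("proportions must be positive and sum to 1")
  }

  if (is.null(interactions)) {
    interactions <- tibble(from = character(), to = character(),
                           V_rev = numeric(), J_bar = numeric(),
                           sigma_J = numeric(), theta = numeric())
  }
  interactions <- as_tibble(interactions)
  need <- c("from", "to", "V_rev", "J_bar", "sigma_J")
  if (any(!need %in% names(interactions))) {
    abort(sprintf("interaction table lacks columns: %s",
                  paste(setdiff(need, names(interactions)), collapse = ", ")))
  }
  if (!"theta" %in% names(interactions)) interactions$theta <- NA_real_
  bad <- setdiff(unique(c(interactions$from, interactions$to)), labels)
  if (length(bad)) {
    abort(sprintf("interaction table references unknown population(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(interactions[c("from", "to")])) {
    abort("duplicated (from, to) pair in interaction table")
  }
  # fill absent ordered pairs with zero coupling
  full <- expand.grid(from = labels, to = labels, stringsAsFactors = FALSE)
  full <- left_join(as_tibble(full), interactions, by = c("from", "to"))
  miss <- is.na(full$V_rev)
  full$V_rev[miss] <- 0; full$J_bar[miss] <- 0; full$sigma_J[miss] <- 0
  if (any(full$J_bar < 0) || any(full$sigma_J < 0)) {
    abort("J_bar and sigma_J must be >= 0")
  }
  if (conductance_model == "sign_preserving") {
    full$theta[miss & is.na(full$theta)] <- 1
    if (any(is.na(full$theta)) || any(full$theta <= 0)) {
      abort("sign-preserving model: every interaction needs theta > 0")
    }
  } else {
    if (any(!is.na(full$theta))) {
      abort("simple conductance model: theta must not be set (it is unused); remove it")
    }
  }
  stopifnot(inherits(chi, "nm_chi"))

  structure(
    list(populations = setNames(populations, labels), labels = labels,
         interactions = full, chi = chi, proportions = proportions,
         conductance_model = conductance_model,
         p_bar = p_bar, ell = p_bar^2 + 6 * p_bar),
    class = "nm_model"
  )
}

#' @export
print.nm_model <- function(x, ...) {
  kinds <- vapply(x$populations, `[[`, "", "model_kind")
  cat(sprintf("<nm_model> %d population(s) [%s], %s conductances, state dim %d\n",
              x$p_bar, paste(sprintf("%s:%s", x$labels, kinds), collapse = ", "),
              x$conductance_model, x$ell))
  invisible(x)
}

#' Ready-made example models
#'
#' `fhn_model_spec()` builds a one-population (or `p`-population)
#' FitzHugh-Nagumo network with sign-preserving conductances and the default
#' trapezoid envelope; `hh_model_spec()` the Hodgkin-Huxley analogue. These
#' are the reference configurations used by the package's own experiments.
#'
#' @param p number of populations.
#' @param J_bar,sigma_J,theta,V_rev interaction parameters applied to every
#'   ordered pair.
#' @param conductance_model `"sign_preserving"` or `"simple"`.
#' @param ... passed to [fhn_population()] / [hh_population()].
#' @return an `nm_model`.
#' @export
fhn_model_spec <- function(p = 1, J_bar = 0.5, sigma_J = 0.2, theta = 0.5,
                           V_rev = 1.0,
                           conductance_model = "sign_preserving", ...) {
  labels <- if (p == 1) "exc" else paste0("pop", seq_len(p))
  pops <- lapply(labels, function(l) fhn_population(l, ...))
  th <- if (conductance_model == "sign_preserving") theta else NA_real_
  inter <- expand.grid(from = labels, to = labels, stringsAsFactors = FALSE)
  inter <- tibble(from = inter$from, to = inter$to, V_rev = V_rev,
                  J_bar = J_bar, sigma_J = sigma_J, theta = th)
  model_spec(pops, inter, conductance_model = conductance_model)
}

#' @rdname fhn_model_spec
#' @export
hh_model_spec <- function(p = 1, J_bar = 0.5, sigma_J = 0.2, theta = 0.5,
                          V_rev = 0,
                          conductance_model = "sign_preserving", ...) {
  labels <- if (p == 1) "exc" else paste0("pop", seq_len(p))
  pops <- lapply(labels, function(l) hh_population(l, ...))
  th <- if (conductance_model == "sign_preserving") theta else NA_real_
  inter <- expand.grid(from = labels, to = labels, stringsAsFactors = FALSE)
  inter <- tibble(from = inter$from, to = inter$to, V_rev = V_rev,
                  J_bar = J_bar, sigma_J = sigma_J, theta = th)
  model_spec(pops, inter, conductance_model = conductance_model)
}

# ---- coefficient functions --------------------------------------------------

#' Sigmoidal transmitter release function
#'
#' `S(v) = C / (1 + exp(-lambda (v - delta)))`: the concentration of
#' transmitter released into the synaptic cleft by a presynaptic neuron at
#' potential `v`. Strictly increasing, valued in (0, C).
#'
#' @param pop an [population_spec()] object.
#' @param v membrane potential(s), mV.
#' @return release concentration(s) in (0, C).
#' @export
sigmoid_eval <- function(pop, v) {
  sg <- pop$sigmoid
  sg$C / (1 + exp(-sg$lambda * (v - sg$delta)))
}

#' FitzHugh-Nagumo membrane drift
#'
#' `F(v, w) = -v^3/3 + v - w`. One-sided Lipschitz in `v` with constant
#' `L = 1` for the damping form `M(v, v') = (|v| - |v'|)^2 / 3`, and Lipschitz
#' in `w`.
#'
#' @param pop an [population_spec()] of kind `"fhn"`.
#' @param v membrane potential.
#' @param w recovery variable.
#' @return the drift value.
#' @export
fhn_drift <- function(pop, v, w) {
  stopifnot(pop$model_kind == "fhn")
  -v^3 / 3 + v - w
}

#' Hodgkin-Huxley membrane drift
#'
#' The classic ionic-current drift
#' `(-g_Na m^3 h (v - E_Na) - g_K n^4 (v - E_K) - g_L (v - E_L) + I_app)/C_m`.
#' Continuous in all arguments and Lipschitz in `(n, m, h)` once `v` is
#' confined to the clipping interval.
#'
#' @param pop an [population_spec()] of kind `"hh"`.
#' @param v membrane potential (mV).
#' @param n,m,h gating proportions.
#' @return the drift value (mV ms^-1).
#' @export
hh_membrane_drift <- function(pop, v, n, m, h) {
  stopifnot(pop$model_kind == "hh")
  p <- pop$hh
  (-p$g_Na * m^3 * h * (v - p$E_Na) -
     p$g_K * n^4 * (v - p$E_K) -
     p$g_L * (v - p$E_L) + p$I_app) / p$C_m
}

#' Drift and diffusion of a gating variable
#'
#' The Langevin channel-noise coefficients for gate `x` in `{n, m, h}`:
#' drift `rho(v) (1 - x) - zeta(v) x` and diffusion
#' `sqrt(|rho(v) (1 - x) + zeta(v) x|) * chi(x)`. The absolute value under the
#' root is retained for discrete-scheme safety (states can transiently sit
#' outside \[0, 1\] mid-step); the envelope chi makes the diffusion vanish at
#' and beyond the boundaries, while the drift points inward there.
#'
#' @param pop an [population_spec()] of kind `"hh"`.
#' @param chi a [chi_fun()] envelope.
#' @param x_name one of `"n"`, `"m"`, `"h"`.
#' @param v membrane potential.
#' @param x gate proportion.
#' @return list with numeric `drift` and `diffusion`.
#' @export
gate_coefficients <- function(pop, chi, x_name, v, x) {
  stopifnot(pop$model_kind == "hh", x_name %in% c("n", "m", "h"))
  rf <- pop$gates[[x_name]]
  rho <- rf$rho(v); zeta <- rf$zeta(v)
  list(drift = rho * (1 - x) - zeta * x,
       diffusion = sqrt(abs(rho * (1 - x) + zeta * x)) * chi_eval(chi, x))
}

#' Drift and diffusion of the synaptic variable
#'
#' Same structure as [gate_coefficients()] with opening rate `a_r S(v)` and
#' closing rate `a_d`: drift `a_r S(v) (1 - y) - a_d y`, diffusion
#' `sqrt(|a_r S(v) (1 - y) + a_d y|) * chi(y)`.
#'
#' @param pop an [population_spec()] object.
#' @param chi a [chi_fun()] envelope.
#' @param v membrane potential.
#' @param y synaptic proportion.
#' @return list with numeric `drift` and `diffusion`.
#' @export
synapse_coefficients <- function(pop, chi, v, y) {
  s <- sigmoid_eval(pop, v)
  list(drift = pop$a_r * s * (1 - y) - pop$a_d * y,
       diffusion = sqrt(abs(pop$a_r * s * (1 - y) + pop$a_d * y)) *
         chi_eval(chi, y))
}

# ---- one-sided Lipschitz estimation ----------------------------------------

#' Estimate a one-sided Lipschitz constant on a grid
#'
#' Computes the grid supremum over pairs `v != v'` (and over `q` in `q_grid`)
#' of
#' `(F(v, q) - F(v', q)) (v - v') / (v - v')^2 + M(v, v')`,
#' the smallest admissible constant `L` in the one-sided Lipschitz condition
#' `(F(v,q) - F(v',q))(v - v') <= L (v - v')^2 - M(v, v') (v - v')^2`.
#' For the FitzHugh-Nagumo drift with `M(v, v') = (|v| - |v'|)^2 / 3` the
#' supremum is 1, attained whenever `v v' = 0`.
#'
#' Pairs with `|v - v'| < 1e-12` are excluded (0/0). The pairwise statistic
#' carries a floating-point rounding noise of order `ulp(|F|/|v - v'|)`; the
#' returned supremum is therefore reported at the instrument's noise floor of
#' 12 significant digits, far below any grid-resolution effect.
#'
#' @param F drift function of two arguments `(v, q)`.
#' @param M damping form, a function of `(v, vp)`; use `function(v, vp) 0`
#'   for a plain one-sided constant.
#' @param v_grid numeric grid of potentials (the supremum is exact at the
#'   grid level when the grid contains 0 and the maximiser has `v v' = 0`).
#' @param q_grid grid of the second argument (default 0; it cancels for
#'   drifts linear in `q`).
#' @return the estimated constant `L_hat` (a scalar).
#' @examples
#' pop <- fhn_population()
#' estimate_one_sided_lipschitz(
#'   function(v, q) fhn_drift(pop, v, q),
#'   function(v, vp) (abs(v) - abs(vp))^2 / 3,
#'   seq(-3, 3, by = 0.1)
#' )
#' @export
estimate_one_sided_lipschitz <- function(F, M, v_grid, q_grid = 0) {
  if (length(v_grid) < 2L) abort("v_grid must contain at least two points")
  if (length(q_grid) < 1L) abort("q_grid must be non-empty")
  nv <- length(v_grid)
  dv <- outer(v_grid, v_grid, "-")
  keep <- abs(dv) >= 1e-12
  if (!any(keep)) abort("no admissible pairs in v_grid")
  va <- matrix(v_grid, nv, nv)
  Mm <- M(va, t(va))  # recycle if M is constant
  if (!is.matrix(Mm)) Mm <- matrix(Mm, nv, nv)
  best <- -Inf
  for (q in q_grid) {
    Fv <- rep_len(F(v_grid, q), nv)
    g <- outer(Fv, Fv, "-") / dv + Mm
    best <- max(best, g[keep])
  }
  signif(best, 12)
}

# ---- hypothesis validation --------------------------------------------------

#' Numerically validate the structural hypotheses of a model
#'
#' Checks, on recorded grids, the conditions under which the N-neuron systems
#' and their mean-field limits are well posed and the proportion variables
#' stay in \[0, 1\]:
#' \itemize{
#'   \item `chi_ok` - the noise envelope is non-negative with compact support
#'     strictly inside (0, 1) and a finite Lipschitz constant;
#'   \item `sigmoid_ok` - sigmoid parameters positive and `S` increasing and
#'     bounded by `C` on the grid;
#'   \item `rates_ok` - for HH populations, the gating rates are bounded below
#'     by a strictly positive constant `nu_hat` on the potential grid (the
#'     coercivity condition);
#'   \item `one_sided_L` - a grid estimate of the one-sided Lipschitz constant
#'     of the membrane drift (for FHN with its exact damping form the estimate
#'     is 1; the classic HH drift does not satisfy a global one-sided
#'     condition, so its estimate is reported for information);
#'   \item `boundary_ok` - the boundary sign/vanishing conditions of the
#'     rectangular-cylinder invariance framework (see
#'     [check_boundary_conditions()]).
#' }
#' Failures are report entries, never exceptions; every flag is reproducible
#' from the recorded grids and the model alone.
#'
#' @param model an [model_spec()] object.
#' @param v_grid potential grid (mV).
#' @param x_grid proportion grid; must extend beyond \[0, 1\] to exercise the
#'   boundary clauses.
#' @return an object of class `nm_hypothesis_report` with a `checks` tibble
#'   (`check`, `population`, `pass`, `value`, `detail`), the grids used, and
#'   an `overall` flag. Supports [tidy()] and [report_to_json()].
#' @export
validate_hypotheses <- function(model,
                                v_grid = seq(-100, 100, by = 0.5),
                                x_grid = seq(-0.5, 1.5, by = 0.005)) {
  stopifnot(inherits(model, "nm_model"))
  rows <- list()
  add <- function(check, population, pass, value, detail) {
    rows[[length(rows) + 1L]] <<- tibble(
      check = check, population = population, pass = pass,
      value = value, detail = detail)
  }

  ## chi: compact support inside (0,1), non-negative, Lipschitz
  cv <- chi_eval(model$chi, x_grid)
  nonneg <- all(cv >= 0)
  pos <- x_grid[cv > 0]
  if (length(pos)) {
    supp <- range(pos)
    compact <- supp[1] > 0 && supp[2] < 1 &&
      all(cv[x_grid <= 0 | x_grid >= 1] == 0)
  } else {
    supp <- c(NA_real_, NA_real_); compact <- FALSE  # chi == 0: degenerate
  }
  lip_hat <- if (length(x_grid) > 1) max(abs(diff(cv) / diff(x_grid))) else NA
  add("chi_ok", NA_character_, nonneg && compact, lip_hat,
      sprintf("support [%.3g, %.3g], Lipschitz ~ %.3g",
              supp[1], supp[2], lip_hat))

  for (pop in model$populations) {
    lab <- pop$label
    ## sigmoid
    sv <- sigmoid_eval(pop, v_grid)
    # non-strict comparisons: the sigmoid saturates to 0/C in double
    # precision at the grid extremes although it is strictly monotone
    sig_ok <- pop$sigmoid$C > 0 && pop$sigmoid$lambda > 0 &&
      all(diff(sv) >= 0) && any(diff(sv) > 0) &&
      all(sv >= 0 & sv <= pop$sigmoid$C) &&
      pop$a_r > 0 && pop$a_d > 0
    add("sigmoid_ok", lab, sig_ok, pop$sigmoid$C,
        sprintf("S increasing on grid, bounded by C = %g", pop$sigmoid$C))

    ## gating-rate coercivity (HH only)
    if (pop$model_kind == "hh") {
      nu_hat <- min(vapply(pop$gates, function(rf) {
        min(rf$rho(v_grid), rf$zeta(v_grid))
      }, numeric(1)))
      add("rates_ok", lab, nu_hat > 0, nu_hat,
          sprintf("nu_hat = min over grid of rho ^ zeta = %.4g ms^-1", nu_hat))
    } else {
      add("rates_ok", lab, TRUE, NA_real_, "no gating variables (FHN)")
    }

    ## one-sided Lipschitz constant of the membrane drift
    if (pop$model_kind == "fhn") {
      vg <- seq(-3, 3, by = 0.01)
      L_hat <- estimate_one_sided_lipschitz(
        function(v, q) fhn_drift(pop, v, q),
        function(v, vp) (abs(v) - abs(vp))^2 / 3, vg)
      add("one_sided_L", lab, is.finite(L_hat), L_hat,
          "M(v,v') = (|v|-|v'|)^2/3; grid [-3,3] step 0.01")
    } else {
      q0 <- c(0.3177, 0.0529, 0.5961)  # resting gates
      L_hat <- estimate_one_sided_lipschitz(
        function(v, q) hh_membrane_drift(pop, v, q0[1], q0[2], q0[3]),
        function(v, vp) 0, seq(-100, 100, by = 1))
      add("one_sided_L", lab, is.finite(L_hat), L_hat,
          "M = 0, gates at rest; HH drift has no global one-sided constant")
    }
  }

  ## boundary conditions (invariance framework)
  bc <- check_boundary_conditions(model, x_grid = x_grid, v_grid = v_grid)
  for (i in seq_len(nrow(bc))) {
    add("boundary_ok", bc$population[i], bc$pass[i], NA_real_,
        sprintf("%s: %s", bc$variable[i], bc$detail[i]))
  }

  checks <- bind_rows(rows)
  structure(
    list(checks = checks, overall = all(checks$pass),
         grids = list(v_grid = v_grid, x_grid = x_grid)),
    class = "nm_hypothesis_report"
  )
}

#' @export
print.nm_hypothesis_report <- function(x, ...) {
  cat(sprintf("<nm_hypothesis_report> overall: %s\n",
              if (x$overall) "PASS" else "FAIL"))
  df <- as.data.frame(x$checks)
  df$detail <- substr(df$detail, 1, 48)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize a hypothesis report to JSON
#'
#' @param report an object returned by [validate_hypotheses()].
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "nm_hypothesis_report"))
  obj <- list(overall = report$overall, checks = report$checks,
              grids = list(v_grid = range(report$grids$v_grid),
                           x_grid = range(report$grids$x_grid)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
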