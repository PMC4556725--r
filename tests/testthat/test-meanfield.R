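closed_form_ybar <- function(a_r, a_d, y0, s, t) {
  # constant-release linear ODE solved exactly
  yst <- a_r * s / (a_d + a_r * s)
  yst + (y0 - yst) * exp(-(a_d + a_r * s) * t)
}

test_that("ybar closed form: decay, initial value, constant-release solution", {
  tt <- seq(0, 5, by = 1e-3)
  # vanishing release: pure exponential decay
  yb <- ybar_from_sbar(1, 0.3, 0.4, rep(0, length(tt)), tt)
  expect_equal(yb, 0.4 * exp(-0.3 * tt), tolerance = 1e-12)
  expect_identical(yb[1], 0.4)
  # constant release vs the exact solution
  yb2 <- ybar_from_sbar(1, 0.3, 0.2, rep(0.5, length(tt)), tt)
  expect_lt(max(abs(yb2 - closed_form_ybar(1, 0.3, 0.2, 0.5, tt))), 1e-4)
  expect_true(all(yb2 >= 0 & yb2 <= 1))
  # input validation
  expect_error(ybar_from_sbar(1, 0.3, 0.2, c(-0.1, 0.1), c(0, 1)), "non-negative")
  expect_error(ybar_from_sbar(1, 0.3, 1.2, c(0, 0), c(0, 1)), "0, 1")
})

test_that("quadrature error scales as O(dt^2)", {
  err <- vapply(c(1e-2, 5e-3, 2.5e-3), function(dt) {
    tt <- seq(0, 2, by = dt)
    yb <- ybar_from_sbar(1, 0.3, 0.2, rep(0.5, length(tt)), tt)
    max(abs(yb - closed_form_ybar(1, 0.3, 0.2, 0.5, tt)))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)
  expect_lt(err[1] / err[2], 5.5)
  expect_gt(err[2] / err[3], 3)
  expect_lt(err[2] / err[3], 5.5)
})

test_that("limit ensembles are deterministic and MC error shrinks ~ 1/sqrt(M)", {
  m <- fhn1()
  tt <- seq(0, 1, by = 1e-2)
  mf <- dplyr::bind_rows(lapply(m$labels, function(l) {
    tibble::tibble(time = tt, population = l, ybar = 0.4)
  }))
  e1 <- simulate_limit_ensemble(m, mf, M = 50, dt = 1e-2, seed = 8)
  e2 <- simulate_limit_ensemble(m, mf, M = 50, dt = 1e-2, seed = 8)
  expect_identical(e1$sbar, e2$sbar)
  expect_identical(e1$traj$V, e2$traj$V)

  # spread of the terminal release estimate over independent seeds
  spread <- function(M) {
    ends <- vapply(1:8, function(s) {
      ens <- simulate_limit_ensemble(m, mf, M = M, dt = 1e-2, seed = 100 + s)
      ens$sbar[nrow(ens$sbar), 1]
    }, numeric(1))
    sd(ends)
  }
  r <- spread(400) / spread(100)
  expect_gt(r, 0.25)
  expect_lt(r, 0.85)  # ideal 0.5, wide band for 8 seeds
})

test_that("with zero interaction the limit copies have the network law", {
  m <- fhn_model_spec(J_bar = 0, sigma_J = 0)
  tt <- seq(0, 1, by = 1e-3)
  mf <- tibble::tibble(time = tt, population = "exc", ybar = 0.5)
  ens <- simulate_limit_ensemble(m, mf, M = 400, dt = 1e-3, seed = 61)
  # 400 uncoupled network neurons = 400 iid copies of the N = 1 system
  lay <- population_layout(m, 400)
  init <- sample_initial_conditions(m, layout = lay, seed = 62)
  tr <- simulate_network(m, lay, init, T = 1, dt = 1e-3, seed = 63,
                         stride = 1000)
  ks <- suppressWarnings(stats::ks.test(ens$traj$V[nrow(ens$traj$V), ],
                                        tr$V[nrow(tr$V), ]))
  expect_gt(ks$p.value, 0.01)
})

test_that("Picard iteration: fixed point after one corrective pass without coupling", {
  m <- fhn_model_spec(J_bar = 0, sigma_J = 0)
  mf <- picard_solve(m, T = 1, dt = 1e-3, M = 200, tol = 1e-2, seed = 71)
  res <- attr(mf, "residuals")
  # V does not depend on ybar, so sbar is fixed from the first ensemble
  expect_identical(attr(mf, "iterations"), 2L)
  expect_lt(res[2], 1e-2)
  expect_true(all(mf$ybar >= 0 & mf$ybar <= 1))
})

test_that("Picard residuals decrease and the solve is reproducible", {
  m <- fhn1()
  mf <- picard_solve(m, T = 2, dt = 1e-3, M = 400, tol = 5e-3, seed = 81)
  res <- attr(mf, "residuals")
  expect_true(all(diff(res) < 0))
  mf2 <- picard_solve(m, T = 2, dt = 1e-3, M = 400, tol = 5e-3, seed = 81)
  expect_identical(mf$sbar, mf2$sbar)
  g <- glance(mf)
  expect_lt(g$final_residual, 5e-3)
  expect_true(is.finite(g$ybar_gap))

  # non-convergence raises a condition carrying the residual history
  expect_error(
    picard_solve(m, T = 2, dt = 1e-3, M = 400, tol = 1e-12, max_iter = 2,
                 seed = 81),
    class = "mfneuron_picard_nonconvergence")
})

test_that("absorbing synapse: zero release keeps ybar at zero", {
  tt <- seq(0, 3, by = 1e-2)
  yb <- ybar_from_sbar(0, 0.3, 0, rep(0, length(tt)), tt)
  expect_identical(yb, rep(0, length(tt)))
})

test_that("two-population Picard solve produces per-population paths", {
  m <- fhn2()
  mf <- picard_solve(m, T = 1, dt = 2e-3, M = 200, tol = 2e-2, seed = 91)
  td <- tidy(mf)
  expect_setequal(unique(td$population), c("a", "b"))
  expect_true(all(td$ybar >= 0 & td$ybar <= 1))
  expect_true(all(td$sbar >= 0 & td$sbar <= 1))
})
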