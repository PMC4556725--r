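test_that("sigmoid evaluates the release formula and is monotone bounded", {
  pop <- population_spec("p", "fhn", sigmoid = list(C = 1, lambda = 1, delta = 0))
  expect_identical(sigmoid_eval(pop, 0), 0.5)  # S(delta) = C/2
  expect_lt(sigmoid_eval(pop, -1e3), 1e-12)    # lower asymptote

  pop2 <- population_spec("p", "fhn", sigmoid = list(C = 2, lambda = 0.5, delta = 1))
  expect_equal(sigmoid_eval(pop2, 3), 2 / (1 + exp(-1)), tolerance = 1e-15)

  v <- seq(-50, 50, by = 0.25)
  sv <- sigmoid_eval(pop2, v)
  expect_true(all(diff(sv) > 0))
  expect_true(all(sv > 0 & sv < 2))
})

test_that("noise envelope has compact support, peak plateau, finite Lipschitz", {
  ch <- chi_fun()  # trapezoid on (0.05, 0.95), flat on [0.1, 0.9]
  expect_identical(chi_eval(ch, c(0, 1, -0.3, 1.2, 0.05, 0.95)), rep(0, 6))
  expect_identical(chi_eval(ch, c(0.1, 0.5, 0.9)), rep(1, 3))
  expect_equal(chi_eval(ch, 0.075), 0.5)  # mid-ramp
  expect_equal(ch$lipschitz, 20)

  cb <- chi_fun("cosine_bump", lo = 0.2, hi = 0.8)
  x <- seq(-0.5, 1.5, by = 0.01)
  vals <- chi_eval(cb, x)
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(vals[x <= 0.2 | x >= 0.8] == 0))
  expect_equal(chi_eval(cb, 0.5), 1)

  expect_error(chi_fun(lo = 0, hi = 0.9), "support")
  expect_error(chi_fun(lo = 0.4, hi = 0.5, ramp = 0.2), "ramp")
})

test_that("FHN drift matches the cubic formula", {
  pop <- fhn_population()
  expect_identical(fhn_drift(pop, 0, 0), 0)
  expect_equal(fhn_drift(pop, 1, 0), 2 / 3)
  expect_equal(fhn_drift(pop, 2, 5), -17 / 3)
})

test_that("HH membrane drift agrees with an independent evaluation", {
  pop <- hh_population()
  # leak-free limit: all conductances zero -> drift equals the input current
  pop0 <- population_spec("h", "hh", hh = list(
    g_Na = 0, E_Na = 50, g_K = 0, E_K = -77, g_L = 0, E_L = -54.4,
    C_m = 1, I_app = 3.25))
  expect_identical(hh_membrane_drift(pop0, -65, 0.3, 0.05, 0.6), 3.25)
  # leak-only equilibrium
  popL <- population_spec("h", "hh", hh = list(
    g_Na = 0, E_Na = 50, g_K = 0, E_K = -77, g_L = 0.3, E_L = -54.387,
    C_m = 1, I_app = 0))
  expect_identical(hh_membrane_drift(popL, -54.387, 0, 0, 0), 0)
  # independent re-implementation at resting gates
  v <- -65; n <- 0.3177; m <- 0.0529; h <- 0.5961
  p <- pop$hh
  I_Na <- p$g_Na * m * m * m * h * (v - p$E_Na)
  I_K <- p$g_K * n * n * n * n * (v - p$E_K)
  I_L <- p$g_L * (v - p$E_L)
  expect_equal(hh_membrane_drift(pop, v, n, m, h),
               (p$I_app - I_Na - I_K - I_L) / p$C_m, tolerance = 1e-12)
})

test_that("gate and synapse coefficients respect the boundary contracts", {
  pop <- hh_population()
  ch <- chi_fun()
  for (g in c("n", "m", "h")) {
    for (v in c(-80, -65, -20, 10)) {
      c0 <- gate_coefficients(pop, ch, g, v, 0)
      c1 <- gate_coefficients(pop, ch, g, v, 1)
      expect_identical(c0$drift, pop$gates[[g]]$rho(v))
      expect_gt(c0$drift, 0)
      expect_identical(c0$diffusion, 0)
      expect_identical(c1$drift, -pop$gates[[g]]$zeta(v))
      expect_lt(c1$drift, 0)
      expect_identical(c1$diffusion, 0)
    }
  }
  # coercivity: the square-root argument is bounded below by the rate floor
  # for every x in [0, 1]
  xs <- seq(0, 1, by = 0.05)
  for (g in c("n", "m", "h")) {
    for (v in c(-90, -65, 0, 90)) {
      rho <- pop$gates[[g]]$rho(v); zeta <- pop$gates[[g]]$zeta(v)
      expect_true(all(rho * (1 - xs) + zeta * xs >= pop$floor_rate))
    }
  }

  # synapse arithmetic with a_r = a_d = 1 and S(v) = 0.5 at v = delta
  popf <- population_spec("f", "fhn", a_r = 1, a_d = 1,
                          sigmoid = list(C = 1, lambda = 1, delta = 0))
  sc <- synapse_coefficients(popf, ch, v = 0, y = 0.25)
  expect_equal(sc$drift, 0.125)
  expect_equal(sc$diffusion, sqrt(0.625))
  expect_identical(synapse_coefficients(popf, ch, 0, 0)$diffusion, 0)
  expect_equal(synapse_coefficients(popf, ch, 0, 1)$drift, -1)
})

test_that("one-sided Lipschitz estimator: FHN constant is exactly 1", {
  pop <- fhn_population()
  Ffun <- function(v, q) fhn_drift(pop, v, q)
  Mfun <- function(v, vp) (abs(v) - abs(vp))^2 / 3
  L <- estimate_one_sided_lipschitz(Ffun, Mfun, seq(-3, 3, by = 0.1))
  expect_identical(L, 1)

  # linear contraction: the quotient is identically -k
  k <- 0.7
  Lk <- estimate_one_sided_lipschitz(function(v, q) -k * v,
                                     function(v, vp) 0,
                                     seq(-2, 2, by = 0.25))
  expect_equal(Lk, -k)

  L0 <- estimate_one_sided_lipschitz(function(v, q) 5, function(v, vp) 0,
                                     seq(-1, 1, by = 0.5))
  expect_identical(L0, 0)

  expect_error(estimate_one_sided_lipschitz(Ffun, Mfun, numeric(0)), "two points")
  expect_error(estimate_one_sided_lipschitz(Ffun, Mfun, 1), "two points")
})

test_that("hypothesis validation passes compliant models and flags violations", {
  rep1 <- validate_hypotheses(fhn1())
  expect_true(rep1$overall)
  expect_true(all(rep1$checks$pass))
  L_row <- rep1$checks[rep1$checks$check == "one_sided_L", ]
  expect_identical(L_row$value, 1)

  # constant envelope: compact-support and boundary conditions must fail
  bad <- model_spec(list(fhn_population()), fhn1()$interactions,
                    chi = chi_fun("constant"))
  repb <- validate_hypotheses(bad)
  expect_false(repb$overall)
  expect_false(repb$checks$pass[repb$checks$check == "chi_ok"])
  expect_false(all(repb$checks$pass[repb$checks$check == "boundary_ok"]))

  # HH: coercivity holds with the floored rates
  reph <- validate_hypotheses(hh1())
  expect_true(reph$overall)
  nu <- reph$checks$value[reph$checks$check == "rates_ok"]
  expect_gte(nu, 1e-3)

  # JSON serialization round-trips the flags
  js <- report_to_json(rep1)
  parsed <- jsonlite::fromJSON(js)
  expect_true(parsed$overall)
  expect_equal(nrow(parsed$checks), nrow(rep1$checks))
})

test_that("model spec derives dimensions and enforces structure", {
  m <- fhn2()
  expect_identical(m$p_bar, 2L)
  expect_identical(m$ell, 2^2 + 6 * 2)
  expect_error(model_spec(list(fhn_population("a")), proportions = c(b = 1)),
               "named")
  expect_error(
    model_spec(list(fhn_population("a"), fhn_population("b")),
               proportions = c(a = 0.7, b = 0.7)),
    "sum to 1")
  expect_error(
    model_spec(list(fhn_population("a")),
               interaction_spec("a", "zz", theta = 1)),
    "unknown population")
  # simple model rejects theta
  expect_error(
    model_spec(list(fhn_population("a")),
               interaction_spec("a", "a", theta = 1),
               conductance_model = "simple"),
    "theta")
})
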