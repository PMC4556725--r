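test_that("population synaptic input averages y over the population", {
  m <- fhn2()
  lay <- population_layout(m, 4)  # 2 + 2 neurons
  st <- network_state(0, lay$assignment, lay$stream_id,
                      V = rep(0, 4), y = c(0.2, 0.4, 0.5, 0.5),
                      J = matrix(0.5, 4, 2))
  expect_equal(population_synaptic_input(st, lay, "a"), 0.3)
  expect_equal(population_synaptic_input(st, lay, "b"), 0.5)
  st0 <- network_state(0, lay$assignment, lay$stream_id,
                       V = rep(0, 4), y = rep(0, 4), J = matrix(0, 4, 2))
  expect_identical(population_synaptic_input(st0, lay, "b"), 0)
  expect_error(population_synaptic_input(st, lay, "zz"), "unknown population")
})

test_that("layout enforces the fixed proportions", {
  m <- fhn2()  # proportions 0.5 / 0.5
  expect_error(population_layout(m, 5), "incompatible")
  lay <- population_layout(m, 6)
  expect_identical(unname(lay$counts), c(3L, 3L))
})

test_that("CIR step: fixed point, absorption at zero, positivity, mean", {
  expect_identical(cir_step(1.5, 0.8, 1.5, 0, 0.01, 0.3), 1.5)  # J = J_bar, sigma 0
  for (z in c(-3, 0, 2)) {
    expect_identical(cir_step(0, 0.8, 0, 0.5, 0.01, z), 0)  # absorbing at 0
  }
  expect_error(cir_step(-0.1, 1, 1, 0.3, 0.01, 0), "negative")
  # deterministic relaxation
  expect_equal(cir_step(2, 0.5, 1, 0, 0.01, 0), 2 + 0.5 * (1 - 2) * 0.01)

  # Monte-Carlo mean vs the closed-form CIR mean
  set.seed(7)
  npaths <- 4000; dt <- 1e-3; theta <- 1; Jbar <- 1; sJ <- 0.4; J0 <- 2
  J <- rep(J0, npaths); tend <- 0.5
  for (k in seq_len(round(tend / dt))) {
    J <- cir_step(J, theta, Jbar, sJ, dt, rnorm(npaths, sd = sqrt(dt)))
  }
  expect_true(all(J >= 0))
  mexp <- Jbar + (J0 - Jbar) * exp(-theta * tend)
  expect_lt(abs(mean(J) - mexp), 3 * sd(J) / sqrt(npaths))
})

test_that("noise-free single neuron reproduces explicit Euler for the FHN ODE", {
  m <- fhn_model_spec(J_bar = 0, sigma_J = 0, sigma_V = 0)
  st <- state1(m, V = 0.5, y = 0.3, w = 0.1, J = matrix(0, 1, 1))
  dt <- 1e-3
  # independent explicit-Euler oracle, written from the equations directly
  pop <- m$populations[[1]]
  v <- 0.5; y <- 0.3; w <- 0.1
  nstep <- 200L
  for (k in seq_len(nstep)) {
    s <- pop$sigmoid$C / (1 + exp(-pop$sigmoid$lambda * (v - pop$sigmoid$delta)))
    v2 <- v + (-v^3 / 3 + v - w) * dt
    y2 <- y + (pop$a_r * s * (1 - y) - pop$a_d * y) * dt
    w2 <- w + pop$fhn$c * (v + pop$fhn$a - pop$fhn$b * w) * dt
    v <- v2; y <- y2; w <- w2
  }
  lay <- population_layout(m, 1)
  tr <- simulate_network(m, lay, st, T = nstep * dt, dt = dt, seed = 1,
                         stride = nstep,
                         .increments = list(V = matrix(0, nstep, 1),
                                            y = matrix(0, nstep, 1),
                                            B = list(matrix(0, nstep, 1))))
  expect_equal(tr$V[2, 1], v, tolerance = 1e-12)
  expect_equal(tr$y[2, 1], y, tolerance = 1e-12)
  expect_equal(tr$w[2, 1], w, tolerance = 1e-12)
})

test_that("runs are deterministic given the seed and noiseless pairs coincide", {
  m <- fhn1()
  lay <- population_layout(m, 6)
  init <- sample_initial_conditions(m, layout = lay, seed = 3)
  a <- simulate_network(m, lay, init, T = 0.5, dt = 1e-3, seed = 4)
  b <- simulate_network(m, lay, init, T = 0.5, dt = 1e-3, seed = 4)
  expect_identical(a$V, b$V)
  expect_identical(a$y, b$y)
  expect_identical(a$J, b$J)

  # no randomness at all: two uncoupled neurons from the same point follow
  # the same deterministic path
  pops <- list(population_spec("q", "fhn", sigma_V = 0))
  m0 <- model_spec(pops, interaction_spec("q", "q", J_bar = 0, sigma_J = 0,
                                          theta = 0.5),
                   chi = chi_fun(peak = 0))
  lay0 <- population_layout(m0, 2)
  st <- network_state(0, lay0$assignment, lay0$stream_id,
                      V = c(0.4, 0.4), y = c(0.3, 0.3), w = c(0, 0),
                      J = matrix(0, 2, 1))
  tr <- simulate_network(m0, lay0, st, T = 1, dt = 1e-3, seed = 5, stride = 50)
  expect_identical(tr$V[, 1], tr$V[, 2])
  expect_identical(tr$y[, 1], tr$y[, 2])
})

test_that("permuting neurons with their stream ids permutes output bit-identically", {
  m <- fhn1()
  lay1 <- population_layout(m, 8)
  perm <- c(5L, 2L, 7L, 1L, 8L, 3L, 6L, 4L)
  lay2 <- population_layout(m, 8, stream_id = lay1$stream_id[perm])
  init1 <- sample_initial_conditions(m, layout = lay1, seed = 11)
  init2 <- sample_initial_conditions(m, layout = lay2, seed = 11)
  expect_identical(init1$V[perm], init2$V)
  tr1 <- simulate_network(m, lay1, init1, T = 0.5, dt = 1e-3, seed = 12)
  tr2 <- simulate_network(m, lay2, init2, T = 0.5, dt = 1e-3, seed = 12)
  expect_identical(tr1$V[, perm], tr2$V)
  expect_identical(tr1$y[, perm], tr2$y)
  expect_identical(tr1$w[, perm], tr2$w)
})

test_that("proportion variables stay in [0, 1] along default runs", {
  m <- fhn1()
  lay <- population_layout(m, 20)
  init <- sample_initial_conditions(m, layout = lay, seed = 21)
  tr <- simulate_network(m, lay, init, T = 0.5, dt = 1e-4, seed = 22,
                         stride = 50)
  ex <- excursion_stats(tr)
  expect_identical(ex$fraction_inside, 1)
  expect_identical(ex$n_outside, 0)
  expect_true(all(tr$J >= 0))

  # at the coarser dt = 1e-3 the Euler step can occasionally jump through
  # the 0.05-wide envelope ramp: excursions, if any, must be counted and
  # shallow, never silently fixed
  tr2 <- simulate_network(m, lay, init, T = 2, dt = 1e-3, seed = 22,
                          stride = 200)
  ex2 <- excursion_stats(tr2)
  expect_lt(ex2$n_outside / ex2$n_samples, 1e-3)
  expect_lt(ex2$max_distance, 0.05)
})

test_that("strong dt-convergence under shared noise is in the Euler range", {
  m <- fhn_model_spec(J_bar = 0, sigma_J = 0)  # uncoupled, noisy
  npaths <- 16L
  dt4 <- 2.5e-4; Tend <- 1
  n4 <- round(Tend / dt4)
  set.seed(31)
  zV <- matrix(rnorm(n4 * npaths), n4, npaths)
  zy <- matrix(rnorm(n4 * npaths), n4, npaths)
  agg <- function(z, f) {
    # sum f consecutive standard normals and renormalise: z_coarse = sum/sqrt(f)
    nr <- nrow(z) / f
    out <- matrix(0, nr, ncol(z))
    for (j in seq_len(f)) out <- out + z[seq(j, nrow(z), by = f), , drop = FALSE]
    out / sqrt(f)
  }
  lay <- population_layout(m, npaths)
  st <- network_state(0, lay$assignment, lay$stream_id,
                      V = rep(0.2, npaths), y = rep(0.5, npaths),
                      w = rep(0, npaths), J = matrix(0, npaths, 1))
  VT <- function(f) {
    dt <- dt4 * f; n <- n4 / f
    inc <- list(V = agg(zV, f), y = agg(zy, f), B = list(matrix(0, n, npaths)))
    tr <- simulate_network(m, lay, st, T = Tend, dt = dt, seed = 1, stride = n,
                           .increments = inc)
    tr$V[2, ]
  }
  vref <- VT(1); v2 <- VT(2); v4 <- VT(4)
  e2 <- sqrt(mean((v2 - vref)^2))
  e4 <- sqrt(mean((v4 - vref)^2))
  order_hat <- log2(e4 / e2)
  expect_gt(order_hat, 0.3)
  expect_lt(order_hat, 1.7)
})

test_that("second moments stay bounded and stable under dt halving", {
  m <- fhn1()
  lay <- population_layout(m, 100)
  init <- sample_initial_conditions(m, layout = lay, seed = 41)
  stat <- function(dt) {
    tr <- simulate_network(m, lay, init, T = 1, dt = dt, seed = 42,
                           stride = round(0.1 / dt))
    max(rowMeans(tr$V^2))
  }
  m1 <- stat(1e-3); m2 <- stat(5e-4)
  expect_true(is.finite(m1) && is.finite(m2))
  expect_lt(abs(log(m1 / m2)), log(1.5))  # no blow-up, dt-stable
})
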