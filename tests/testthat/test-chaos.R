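test_that("zero-interaction coupling is exactly the identity", {
  m <- fhn_model_spec(J_bar = 0, sigma_J = 0)
  laws <- init_law_spec(m)
  mf <- picard_solve(m, T = 0.5, dt = 1e-3, M = 100, tol = 5e-2, seed = 2)
  for (N in c(4, 10)) {
    lay <- population_layout(m, N)
    run <- simulate_coupled(m, lay, mf, T = 0.5, dt = 1e-3, seed = 3,
                            laws = laws)
    expect_identical(run$network$V, run$limit$V)
    expect_identical(run$network$y, run$limit$y)
    for (i in seq_len(N)) expect_identical(coupling_error(run, i), 0)
    expect_identical(run$sup_tracked, 0)
  }
})

test_that("coupling error is the sup of the summed squared deviation", {
  # hand-built two-snapshot run with a known deviation profile
  mk_traj <- function(V, y, w) {
    structure(list(times = c(0, 1), pop = 1L, labels = "exc",
                   V = V, y = y, w = w, n = NULL, m = NULL, h = NULL,
                   J = NULL, excursions = tibble::tibble()),
              class = "nm_trajectory")
  }
  lay <- structure(list(assignment = 1L, labels = "exc", N = 1L,
                        stream_id = 1L, counts = c(exc = 1L)),
                   class = "nm_layout")
  a <- mk_traj(V = matrix(c(0, 0.3), 2, 1), y = matrix(c(0, 0.4), 2, 1),
               w = matrix(0, 2, 1))
  b <- mk_traj(V = matrix(0, 2, 1), y = matrix(0, 2, 1), w = matrix(0, 2, 1))
  run <- structure(list(network = a, limit = b, layout = lay),
                   class = "nm_coupling")
  expect_equal(coupling_error(run, 1L), 0.3^2 + 0.4^2)  # 0.25 at snapshot 2

  # index multiplicity is enforced
  m2 <- fhn2()
  mf2 <- picard_solve(m2, T = 0.2, dt = 2e-3, M = 60, tol = 0.1, seed = 5)
  lay2 <- population_layout(m2, 4)
  run2 <- simulate_coupled(m2, lay2, mf2, T = 0.2, dt = 2e-3, seed = 6)
  expect_error(coupling_error(run2, c(1L, 2L)), "one neuron of each population")
  expect_error(coupling_error(run2, c(1L)), "one neuron of each population")
  expect_gte(coupling_error(run2, c(1L, 3L)), 0)
})

test_that("the coupled conductance paths are the identical sample paths", {
  m <- fhn1()  # sign-preserving, J_bar > 0
  mf <- picard_solve(m, T = 0.5, dt = 1e-3, M = 100, tol = 5e-2, seed = 7)
  lay <- population_layout(m, 6)
  run <- simulate_coupled(m, lay, mf, T = 0.5, dt = 1e-3, seed = 8)
  expect_identical(run$network$J, run$limit$J)
  # and at t = 0 the whole states coincide
  expect_identical(run$network$V[1, ], run$limit$V[1, ])
  expect_identical(run$network$y[1, ], run$limit$y[1, ])
})

test_that("chaos scan reports the table, errors on bad N, handles zero coupling", {
  m <- fhn1()
  mf <- picard_solve(m, T = 0.5, dt = 1e-3, M = 200, tol = 1e-2, seed = 9)
  sc <- chaos_scan(m, c(5, 10), replications = 4, T = 0.5, dt = 1e-3,
                   base_seed = 10, meanfield = mf, bootstrap = 20)
  expect_s3_class(sc, "nm_chaos_scan")
  expect_identical(sc$N, c(5L, 10L))
  expect_true(all(sc$D_hat >= 0))
  expect_true(all(sc$sqrtN_D == sqrt(sc$N) * sc$D_hat))
  g <- glance(sc)
  expect_true(is.finite(g$slope) || is.na(g$slope))

  m2 <- fhn2()  # proportions 0.5/0.5: odd N impossible
  expect_error(chaos_scan(m2, c(5, 10), replications = 2, T = 0.2, dt = 2e-3,
                          base_seed = 1, meanfield = mf), "incompatible")

  m0 <- fhn_model_spec(J_bar = 0, sigma_J = 0)
  mf0 <- picard_solve(m0, T = 0.2, dt = 2e-3, M = 60, tol = 0.1, seed = 11)
  sc0 <- chaos_scan(m0, c(4, 8), replications = 2, T = 0.2, dt = 2e-3,
                    base_seed = 12, meanfield = mf0, bootstrap = 0)
  expect_identical(sc0$D_hat, c(0, 0))
  expect_true(is.na(attr(sc0, "slope")))  # slope undefined, reported as such
})

test_that("terminal potentials of fixed neurons decorrelate as N grows", {
  m <- fhn1()
  reps <- 48L
  covN <- function(N, seed0) {
    v1 <- numeric(reps); v2 <- numeric(reps)
    for (r in seq_len(reps)) {
      lay <- population_layout(m, N)
      init <- sample_initial_conditions(m, layout = lay, seed = seed0 + r)
      tr <- simulate_network(m, lay, init, T = 1, dt = 2e-3,
                             seed = seed0 + 1000 + r, stride = 500)
      v1[r] <- tr$V[nrow(tr$V), 1]; v2[r] <- tr$V[nrow(tr$V), 2]
    }
    abs(cov(v1, v2))
  }
  c_small <- covN(4, 100)
  c_large <- covN(32, 200)
  expect_lt(c_large, c_small + 0.05)  # decreasing within MC slack
})
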