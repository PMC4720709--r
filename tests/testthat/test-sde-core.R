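# Fundamental matrices, closed-form moments, and Euler-Maruyama simulation.

test_that("fundamental matrix solves the homogeneous drift system", {
  # zero drift: Phi is the identity at every time
  sp0 <- sde_spec(A = matrix(0, 2, 2), B = diag(2), init_mean = c(0, 0))
  expect_equal(fundamental_matrix(sp0, 3.7), diag(2))
  expect_equal(fundamental_matrix(sp0, 0), diag(2))

  # constant diagonal drift: matrix exponential, entrywise exp
  sp1 <- sde_spec(A = diag(0.01, 3), B = diag(3), init_mean = rep(0, 3))
  expect_equal(fundamental_matrix(sp1, 1), diag(exp(0.01), 3),
               tolerance = 1e-12)

  # time-varying scalar drift A(t) = t: closed form exp(t^2 / 2)
  spv <- sde_spec(A = function(t) matrix(t), B = matrix(1), init_mean = 0)
  for (t in c(0.5, 1, 2))
    expect_equal(fundamental_matrix(spv, t)[1, 1], exp(t^2 / 2),
                 tolerance = 1e-8)

  # non-commuting time-varying drift vs brute-force product integration
  Af <- function(t) matrix(c(0, -t, 1, 0.1 * t), 2, 2)
  spnc <- sde_spec(A = Af, B = diag(2), init_mean = c(0, 0))
  expect_equal(fundamental_matrix(spnc, 1.5),
               phi_product_oracle(Af, 0, 1.5),
               tolerance = 1e-6)
})

test_that("invalid drift specifications are rejected", {
  expect_error(sde_spec(A = matrix(NA_real_), B = matrix(1), init_mean = 0),
               "non-finite")
  # drift that turns non-finite inside the integration range
  spbad <- sde_spec(A = function(t) matrix(if (t > 0.5) NaN else 1),
                    B = matrix(1), init_mean = 0)
  expect_error(stacked_moments(spbad, obs_grid(1)), "non-finite")
  sp <- ou_spec(0.1, 80, 1, 1)
  expect_error(fundamental_matrix(sp, -1), ">=")
})

test_that("sde_mean matches closed forms", {
  # no drift, no offset: mean constant at the initial condition
  spc <- sde_spec(A = matrix(0, 2, 2), B = diag(2), init_mean = c(3, -1))
  expect_equal(sde_mean(spc, 7), c(3, -1))

  # Ornstein-Uhlenbeck relaxation towards the optimum
  sp <- ou_spec(beta = 0.1, theta = 80, sigma = 1, xa = 1)
  expect_equal(sde_mean(sp, 30), ou_exact_mean(30, 0.1, 80, 1),
               tolerance = 1e-10)

  # per-coordinate exponential growth under diagonal drift
  fx <- make_fixture("eq33")
  expect_equal(sde_mean(fx$spec1, 20), rep(0.25 * exp(0.2), 3),
               tolerance = 1e-10)
  expect_equal(sde_mean(fx$spec0, 20), rep(0, 3))
})

test_that("sde_cov matches closed forms and degenerate cases", {
  # deterministic dynamics: zero covariance
  spd <- sde_spec(A = diag(0.2, 2), B = matrix(0, 2, 2),
                  init_mean = c(1, 1))
  expect_equal(sde_cov(spd, 2, 5), matrix(0, 2, 2))

  sp <- ou_spec(beta = 0.1, theta = 80, sigma = 1, xa = 1)
  expect_equal(sde_cov(sp, 30, 30)[1, 1], ou_exact_cov(30, 30, 0.1, 1),
               tolerance = 1e-10)
  # cross-covariance, both argument orders
  expect_equal(sde_cov(sp, 10, 20)[1, 1], ou_exact_cov(10, 20, 0.1, 1),
               tolerance = 1e-10)
  expect_equal(sde_cov(sp, 20, 10), t(sde_cov(sp, 10, 20)))

  # a Gaussian initial condition propagates through Phi: 4 e^{-2 * 0.2 * 3}
  spg <- sde_spec(A = matrix(-0.2), B = matrix(0), init_mean = 5,
                  init_cov = matrix(4))
  expect_equal(sde_cov(spg, 3, 3)[1, 1], 4 * exp(-1.2), tolerance = 1e-10)
})

test_that("stacked moments assemble blocks consistently", {
  sp <- ou_spec(0.1, 80, 1, 1)
  # N = 1 degenerates to the pointwise moments
  g1 <- obs_grid(4)
  mom1 <- stacked_moments(sp, g1)
  expect_equal(mom1$mean, sde_mean(sp, 4))
  expect_equal(mom1$cov, sde_cov(sp, 4, 4))

  # blocks equal the pairwise covariance function; matrix is symmetric
  g <- obs_grid(c(1, 2, 3))
  mom <- stacked_moments(sp, g)
  expect_identical(mom$cov, t(mom$cov))
  expect_equal(mom$cov[1, 3], ou_exact_cov(1, 3, 0.1, 1), tolerance = 1e-10)
  expect_equal(mom$mean, ou_exact_mean(1:3, 0.1, 80, 1), tolerance = 1e-10)

  # eq33 stacked covariance is positive definite (full-rank dispersion)
  fx <- make_fixture("eq33")
  S <- stacked_moments(fx$spec0, fx$grid)$cov
  expect_identical(S, t(S))
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("Euler-Maruyama simulation honors the noise-free and seeded contracts", {
  g <- obs_grid(1:5, p = 2)
  spd <- sde_spec(A = matrix(0, 2, 2), B = matrix(0, 2, 2),
                  init_mean = c(2, -3))
  ps <- simulate_paths(spd, g, n = 4, seed = 1)
  expect_true(all(ps$paths[, , 1] == 2) && all(ps$paths[, , 2] == -3))

  sp <- ou_spec(0.1, 80, 1, 1)
  go <- obs_grid(1:10)
  a <- simulate_paths(sp, go, n = 50, seed = 99)
  b <- simulate_paths(sp, go, n = 50, seed = 99)
  expect_identical(a$paths, b$paths)
  c2 <- simulate_paths(sp, go, n = 50, seed = 100)
  expect_false(identical(a$paths, c2$paths))

  # seeding does not disturb the caller's RNG stream
  set.seed(5); x1 <- rnorm(1)
  set.seed(5); invisible(simulate_paths(sp, go, n = 5, seed = 42))
  expect_identical(rnorm(1), x1)
})

test_that("simulated sample moments converge to the closed forms", {
  sp <- ou_spec(0.1, 80, 1, 1)
  g <- obs_grid(1:5)
  n <- 4000
  ps <- simulate_paths(sp, g, n = n, substeps = 50, seed = 31)
  X <- stack_paths(ps)
  m_hat <- colMeans(X)
  m <- ou_exact_mean(1:5, 0.1, 80, 1)
  v <- ou_exact_cov(1:5, 1:5, 0.1, 1)
  expect_true(all(abs(m_hat - m) < 3 * sqrt(v / n)))
  # terminal variance within 3 MC standard errors (SE ~ var * sqrt(2/n))
  v_hat <- var(X[, 5])
  expect_lt(abs(v_hat - v[5]), 3 * v[5] * sqrt(2 / n))
})

test_that("refining the Euler-Maruyama step leaves the terminal mean within MC noise", {
  sp <- ou_spec(0.1, 80, 1, 1)
  g <- obs_grid(1:5)
  # at 100 substeps per unit time the O(dt) scheme bias (~0.006 here) is
  # far inside the Monte-Carlo band, so halving the step moves the
  # terminal mean by noise alone
  n <- 20000
  m1 <- mean(simulate_paths(sp, g, n, substeps = 100, seed = 7)$paths[, 5, 1])
  m2 <- mean(simulate_paths(sp, g, n, substeps = 200, seed = 8)$paths[, 5, 1])
  sdt <- sqrt(ou_exact_cov(5, 5, 0.1, 1))
  expect_lt(abs(m1 - m2), 3 * sqrt(2) * sdt / sqrt(n))
})

test_that("ou_spec maps the trait-evolution model into the linear form", {
  sp <- ou_spec(beta = 0.1, theta = 80, sigma = 1, xa = 1)
  expect_equal(sp$A(0)[1, 1], -0.1)
  expect_equal(sp$a(0)[1, 1], 8)     # beta * theta
  expect_equal(sp$B(0)[1, 1], 1)
  expect_equal(sp$init_mean, 1)

  # beta = 0: Brownian motion about the ancestral state
  bm <- ou_spec(beta = 0, theta = 80, sigma = 2, xa = 3)
  expect_equal(bm$A(1)[1, 1], 0)
  expect_equal(bm$a(1)[1, 1], 0)
  expect_equal(sde_mean(bm, 10), 3)
  expect_equal(sde_cov(bm, 10, 10)[1, 1], 4 * 10, tolerance = 1e-10)

  expect_error(ou_spec(-0.1, 80, 1, 1), "nonnegative")
})
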