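# QDA, OBC and plug-in discriminants over stacked observations.

test_that("QDA discriminant reduces correctly in symmetric cases", {
  m <- c(0, 0); S <- diag(2)
  cl <- qda_classifier(m, S, m, S, alpha1 = 0.5)
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(qda_discriminant(cl, X), rep(0, 10))

  # identical classes, alpha1 = 0.25: only the prior-odds term survives
  cl2 <- qda_classifier(m, S, m, S, alpha1 = 0.25)
  expect_equal(qda_discriminant(cl2, X), rep(-log(1 / 3), 10))
  expect_true(all(predict(cl2, X) == 0L))  # always class 0

  # 1-d equal-variance case: boundary at the midpoint
  cl3 <- qda_classifier(0, matrix(1), 1, matrix(1), alpha1 = 0.5)
  expect_equal(qda_discriminant(cl3, 0.5), 0)
  # log Gaussian density ratio as an independent oracle
  for (x in c(-1, 0.2, 1.7)) {
    expect_equal(qda_discriminant(cl3, x),
                 dnorm(x, 0, 1, log = TRUE) - dnorm(x, 1, 1, log = TRUE))
  }
  # exactly on the boundary the strict > rule assigns class 1
  expect_identical(predict(cl3, 0.5), 1L)
  expect_identical(predict(cl3, 0.49), 0L)
})

test_that("OBC effective density is a normalized multivariate t", {
  params <- list(m = 0.7, Pi = matrix(2.3), k = 5)
  # against the location-scale Student-t built from stats::dt
  xs <- seq(-6, 8, by = 0.37)
  s <- sqrt(2.3)
  expect_equal(obc_log_effective_density(params, matrix(xs, ncol = 1)),
               dt((xs - 0.7) / s, df = 5, log = TRUE) - log(s),
               tolerance = 1e-12)
  # at the location the density equals its normalizing constant
  expect_equal(obc_log_effective_density(params, 0.7),
               lgamma(3) - lgamma(2.5) - 0.5 * log(5 * pi) -
                 0.5 * log(2.3))
  # integrates to one
  f <- function(x) exp(obc_log_effective_density(params,
                                                 matrix(x, ncol = 1)))
  expect_equal(integrate(f, -Inf, Inf, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-6)
  # Gaussian limit at enormous degrees of freedom
  params_big <- list(m = 0, Pi = matrix(1.7), k = 1e6)
  xg <- c(-2, 0, 1, 3)
  expect_equal(obc_log_effective_density(params_big, matrix(xg, ncol = 1)),
               dnorm(xg, 0, sqrt(1.7), log = TRUE), tolerance = 1e-3)
})

test_that("OBC ties and degenerate posteriors resolve to class 0", {
  po <- niw(c(0, 0), diag(2), nu = 5, kappa = 8)
  cl <- build_obc(po, po, alpha1 = 0.5)
  X <- matrix(rnorm(10), 5, 2)
  expect_true(all(predict(cl, X) == 0L))   # tie everywhere
  expect_equal(predict(cl, X, type = "score"), rep(0, 5))
})

test_that("OBC classification matches the brute-force posterior-predictive oracle", {
  set.seed(42)
  draws <- 20000
  checked <- 0
  for (i in 1:40) {
    po0 <- random_niw_2d()
    po1 <- random_niw_2d()
    a1 <- runif(1, 0.2, 0.8)
    cl <- build_obc(po0, po1, alpha1 = a1)
    x <- rnorm(2, sd = 2) + if (runif(1) < 0.5) po0$m else po1$m
    f0 <- niw_pred_mc(po0, x, draws)
    f1 <- niw_pred_mc(po1, x, draws)
    D <- (1 - a1) * f0$mean - a1 * f1$mean
    seD <- sqrt((1 - a1)^2 * f0$se^2 + a1^2 * f1$se^2)
    if (abs(D) > 3 * seD) {
      checked <- checked + 1
      expect_identical(predict(cl, x), if (D >= 0) 0L else 1L)
    }
  }
  expect_gt(checked, 20)  # the oracle actually resolved most instances
})

test_that("OBC converges to QDA with prior moments as certainty grows", {
  sp0 <- ou_spec(0.1, 80, 1, 1)
  sp1 <- ou_spec(0.1, 85, 1, 1)
  g <- obs_grid(1:5)
  Np <- g$dim
  nu <- 1e6; kap <- 1e6 + Np
  pr0 <- prior_from_sde(sp0, g, nu, kap)
  pr1 <- prior_from_sde(sp1, g, nu, kap)
  obc <- build_obc(pr0, pr1, alpha1 = 0.4)
  qda <- build_qda_from_sde(sp0, sp1, g, alpha1 = 0.4)
  te <- rbind(stack_paths(simulate_paths(sp0, g, 150, seed = 1)),
              stack_paths(simulate_paths(sp1, g, 150, seed = 2)))
  expect_identical(predict(obc, te), predict(qda, te))
})

test_that("plug-in classifiers from simulated and analytic moments agree", {
  sp0 <- ou_spec(0.1, 80, 1, 1)
  sp1 <- ou_spec(0.1, 85, 1, 1)
  g <- obs_grid(1:5)
  qa <- build_qda_from_sde(sp0, sp1, g)
  qs <- build_qda_from_sde(sp0, sp1, g, moment_source = "simulated",
                           l = 50000, seed = 9, substeps = 50)
  te <- rbind(stack_paths(simulate_paths(sp0, g, 500, seed = 3)),
              stack_paths(simulate_paths(sp1, g, 500, seed = 4)))
  expect_gte(mean(predict(qa, te) == predict(qs, te)), 0.99)
  expect_error(build_qda_from_sde(sp0, sp1, g,
                                  moment_source = "simulated", l = 5),
               "exceed")
})

test_that("data-driven QDA enforces the sample-size condition", {
  sp <- ou_spec(0.1, 80, 1, 1)
  g <- obs_grid(1:5)
  tr0 <- simulate_paths(sp, g, n = 5, seed = 1, label = 0)  # n = Np
  tr1 <- simulate_paths(sp, g, n = 20, seed = 2, label = 1)
  expect_error(build_qda_from_data(tr0, tr1), "min\\(n0, n1\\) > Np")

  # a duplicated path keeps the covariance PD and the fit well defined
  big <- simulate_paths(sp, g, n = 20, seed = 3, label = 0)
  dup <- big$paths; dup[2, , ] <- dup[1, , ]
  tr0d <- pathset(dup, g, label = 0)
  expect_s3_class(build_qda_from_data(tr0d, tr1), "gp_classifier")
})

test_that("classifier predictions are consistent with exported scores and densities", {
  po0 <- niw(c(0, 0), diag(2) * 2, nu = 4, kappa = 9)
  po1 <- niw(c(1, 1), diag(2), nu = 6, kappa = 12)
  cl <- build_obc(po0, po1, alpha1 = 0.3)
  X <- matrix(rnorm(40), 20, 2)
  s <- log(0.7) + obc_log_effective_density(cl$class0, X) -
    log(0.3) - obc_log_effective_density(cl$class1, X)
  expect_equal(predict(cl, X, type = "score"), s)
  expect_identical(predict(cl, X), ifelse(s >= 0, 0L, 1L))
})
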