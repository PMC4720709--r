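# Shared oracles and generators, independent of the implementation paths
# they are used to check.

# Closed-form Ornstein-Uhlenbeck moments: dX = -beta (X - theta) dt
# + sigma dW, X_0 = xa (constant), started at t0 = 0.
ou_exact_mean <- function(t, beta, theta, xa) {
  if (beta == 0) return(rep(xa, length(t)))
  theta + (xa - theta) * exp(-beta * t)
}
ou_exact_cov <- function(s, t, beta, sigma) {
  # covariance of X_s, X_t for s <= t
  if (beta == 0) return(sigma^2 * pmin(s, t))
  (sigma^2 / (2 * beta)) * exp(-beta * (t - s)) * (1 - exp(-2 * beta * s))
}

# Monte-Carlo posterior-predictive density of a 2-d point under a
# normal-inverse-Wishart parameter bundle: Sigma ~ IW(Psi, kappa),
# mu | Sigma ~ N(m, Sigma / nu), averaged Gaussian density at x.
# Works entirely in closed 2x2 forms so that 1e5 draws stay cheap.
# Entirely independent of the package's Student-t representation.
niw_pred_mc <- function(post, x, draws) {
  W <- stats::rWishart(draws, df = post$kappa, Sigma = solve(post$Psi))
  w11 <- W[1, 1, ]; w12 <- W[1, 2, ]; w22 <- W[2, 2, ]
  detW <- w11 * w22 - w12^2
  # Sigma = W^{-1} entrywise
  s11 <- w22 / detW; s12 <- -w12 / detW; s22 <- w11 / detW
  l11 <- sqrt(s11); l21 <- s12 / l11; l22 <- sqrt(pmax(s22 - l21^2, 0))
  z1 <- stats::rnorm(draws); z2 <- stats::rnorm(draws)
  rt <- sqrt(post$nu)
  mu1 <- post$m[1] + l11 * z1 / rt
  mu2 <- post$m[2] + (l21 * z1 + l22 * z2) / rt
  d1 <- x[1] - mu1; d2 <- x[2] - mu2
  q <- w11 * d1^2 + 2 * w12 * d1 * d2 + w22 * d2^2
  dens <- exp(-q / 2) * sqrt(detW) / (2 * pi)
  list(mean = mean(dens), se = stats::sd(dens) / sqrt(draws))
}

# Random 2-d NIW posterior bundle (integer df so rWishart is happy).
random_niw_2d <- function() {
  Psi <- stats::rWishart(1, df = 6, Sigma = diag(2))[, , 1] + diag(2) * 0.2
  niw(m = stats::rnorm(2, sd = 1.5), Psi = Psi,
      nu = sample(2:20, 1), kappa = sample(6:30, 1))
}

# Crude product-integration of dPhi/dt = A(t) Phi over [t0, t] with step h:
# Phi ~ prod expm(A(s_k) h).  First-order accurate; used as a brute-force
# oracle for time-varying drift.
phi_product_oracle <- function(Afun, t0, t, h = 2e-4) {
  n <- ceiling((t - t0) / h)
  h <- (t - t0) / n
  p <- nrow(Afun(t0))
  Phi <- diag(p)
  for (k in seq_len(n)) {
    s <- t0 + (k - 0.5) * h  # midpoint for second-order accuracy
    Phi <- as.matrix(Matrix::expm(Afun(s) * h)) %*% Phi
  }
  Phi
}

# Tiny eq33-style fixture on a short grid (Np = 9) for fast experiment runs.
small_eq33_config <- function(...) {
  experiment_config("eq33", fixture_overrides = list(N = 3L),
                    n = 12L, kappa = 20, n_test = 50L, reps = 2L,
                    l = 30L, ...)
}
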