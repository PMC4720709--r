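#' Normal-inverse-Wishart parameter bundle
#'
#' The conjugate prior (and posterior) for the mean and covariance of the
#' stacked Gaussian observation: \eqn{\Sigma \sim IW(\Psi, \kappa)},
#' \eqn{\mu \mid \Sigma \sim N(m, \Sigma / \nu)} in dimension
#' \eqn{d = Np}.  \eqn{\nu} and \eqn{\kappa} are certainty knobs: the
#' larger they are, the more concentrated the prior about \eqn{m} and
#' (via the inverse-Wishart mean \eqn{\Psi / (\kappa - d - 1)}) about the
#' SDE-derived covariance.
#'
#' Positive definiteness of `Psi` is verified by a Cholesky factorization
#' attempt; failure raises an error rather than silently regularizing.
#'
#' @param m location vector (length `d`).
#' @param Psi symmetric positive definite `d x d` scale matrix.
#' @param nu mean-confidence scalar, `> 0`.
#' @param kappa covariance-confidence scalar, `> d - 1` for a proper
#'   prior.
#' @return An object of class `niw` with elements `m`, `Psi`, `nu`,
#'   `kappa`, `d` and `n` (number of observations absorbed so far; 0 for a
#'   prior).
#' @seealso [prior_from_sde()], [posterior_update()], [build_obc()]
#' @export
niw <- function(m, Psi, nu, kappa) {
  m <- as.numeric(m)
  d <- length(m)
  Psi <- as.matrix(Psi)
  if (!all(dim(Psi) == d)) stop("'Psi' must be ", d, " x ", d)
  if (max(abs(Psi - t(Psi))) > 1e-8 * max(1, max(abs(Psi))))
    stop("'Psi' must be symmetric")
  Psi <- (Psi + t(Psi)) / 2
  ok <- tryCatch({ chol(Psi); TRUE }, error = function(e) FALSE)
  if (!ok) stop("'Psi' is not positive definite")
  if (nu <= 0) stop("'nu' must be positive")
  if (kappa <= d - 1)
    stop("'kappa' must exceed d - 1 = ", d - 1, " for a proper prior")
  structure(list(m = m, Psi = Psi, nu = nu, kappa = kappa, d = d,
                 n = 0L),
            class = "niw")
}

#' @export
print.niw <- function(x, ...) {
  cat(sprintf(
    "Normal-inverse-Wishart parameters (d = %d): nu = %g, kappa = %g%s\n",
    x$d, x$nu, x$kappa,
    if (x$n > 0L) sprintf(" [posterior after n = %d paths]", x$n) else ""))
  cat("  E[Sigma] exists:",
      if (x$kappa > x$d + 1) "yes" else "no", "\n")
  invisible(x)
}

#' SDE-induced normal-inverse-Wishart prior
#'
#' Maps the Gaussian-process moments implied by a linear SDE on an
#' observation grid into a normal-inverse-Wishart prior whose mean
#' parameters reproduce them: the location is the stacked SDE mean
#' \eqn{m}, and the scale is \eqn{\breve\Psi = (\kappa - Np - 1)\,\Psi} so
#' that the prior mean of the inverse-Wishart covariance equals the SDE
#' covariance \eqn{\Psi} exactly.  The mapping requires
#' \eqn{\kappa > Np + 1} (otherwise the inverse-Wishart mean does not
#' exist).
#'
#' The moments can be taken from the closed forms ([stacked_moments()],
#' the default) or estimated from `l` simulated sample paths
#' ([sde_moment_estimate()]), mirroring the situation where only a
#' simulator for the prior dynamics is available.
#'
#' @inheritParams stacked_moments
#' @param nu mean-confidence hyperparameter, `> 0`.
#' @param kappa covariance-confidence hyperparameter, `> grid$dim + 1`.
#' @param moment_source `"analytic"` for closed-form moments,
#'   `"simulated"` for Monte-Carlo moments from `l` paths.
#' @param l number of simulated paths when `moment_source = "simulated"`.
#' @param seed,substeps passed to the simulator when moments are
#'   simulated.
#' @return A [niw()] prior.
#' @examples
#' sp <- ou_spec(0.1, 80, 1, 1)
#' g <- obs_grid(1:5)
#' pr <- prior_from_sde(sp, g, nu = 25, kappa = 25)
#' max(abs(pr$Psi / (25 - 5 - 1) - stacked_moments(sp, g)$cov))  # ~0
#' @export
prior_from_sde <- function(spec, grid, nu, kappa,
                           moment_source = c("analytic", "simulated"),
                           l = 2000L, seed = NULL, substeps = 10L) {
  check_grid_spec(grid, spec)
  moment_source <- match.arg(moment_source)
  d <- grid$dim
  if (kappa <= d + 1)
    stop("'kappa' must exceed Np + 1 = ", d + 1,
         " for the moment-matching prior mapping")
  if (nu <= 0) stop("'nu' must be positive")
  mom <- if (moment_source == "analytic")
    stacked_moments(spec, grid)
  else
    sde_moment_estimate(spec, grid, l = l, seed = seed, substeps = substeps)
  niw(m = mom$mean, Psi = (kappa - d - 1) * mom$cov, nu = nu,
      kappa = kappa)
}

#' Conjugate posterior update from training sample paths
#'
#' Batch update of a normal-inverse-Wishart prior with a labeled training
#' path set of size \eqn{n}:
#' \deqn{\nu^* = \nu + n, \quad \kappa^* = \kappa + n, \quad
#'       m^* = \frac{\nu m + n \hat\mu}{\nu + n},}
#' \deqn{\Psi^* = \Psi + (n - 1)\hat\Sigma +
#'       \frac{\nu n}{\nu + n}(\hat\mu - m)(\hat\mu - m)^T,}
#' where \eqn{\hat\mu, \hat\Sigma} are the sample mean and unbiased sample
#' covariance of the stacked paths.  A single path (`n = 1`) is allowed:
#' the sample-covariance term then vanishes through its `n - 1` weight.
#' The update is defined batchwise on pooled sufficient statistics;
#' sequential one-path-at-a-time updating is intentionally not offered.
#'
#' @param prior a [niw()] prior (or posterior to be further updated with
#'   an independent batch).
#' @param train a labeled [pathset()] whose stacked dimension matches
#'   `prior$d`.
#' @return A [niw()] posterior with `n` recording the batch size.
#' @export
posterior_update <- function(prior, train) {
  stopifnot(inherits(prior, "niw"), inherits(train, "pathset"))
  X <- stack_paths(train)
  if (ncol(X) != prior$d)
    stop("training paths have stacked dimension ", ncol(X),
         " but the prior has d = ", prior$d)
  n <- nrow(X)
  mu <- colMeans(X)
  dm <- mu - prior$m
  Psi_star <- prior$Psi + (prior$nu * n / (prior$nu + n)) * tcrossprod(dm)
  if (n >= 2L) {
    S <- stats::cov(X)
    Psi_star <- Psi_star + (n - 1) * S
  }
  post <- niw(m = (prior$nu * prior$m + n * mu) / (prior$nu + n),
              Psi = Psi_star,
              nu = prior$nu + n,
              kappa = prior$kappa + n)
  post$n <- n
  post
}
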