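#' Linear vector SDE specification
#'
#' Describes one class-conditional process as the linear (narrow-sense) Ito
#' stochastic differential equation
#' \deqn{dX_t = (A(t) X_t + a(t))\,dt + B(t)\,dW_t, \qquad X_{t_0} = c,}
#' where \eqn{A(t)} is a \eqn{p \times p} drift matrix, \eqn{a(t)} a
#' \eqn{p}-vector drift offset, \eqn{B(t)} a \eqn{p \times q} dispersion
#' matrix and \eqn{W} a \eqn{q}-dimensional standard Wiener process.  The
#' solution is a Gaussian process whenever the initial condition \eqn{c} is
#' constant or Gaussian, which is exactly the class of processes this
#' package classifies.
#'
#' Coefficients may be supplied either as constant matrices/vectors or as
#' functions of time returning objects of the right dimension.  Constant
#' coefficients unlock the matrix-exponential fast path for the fundamental
#' matrix; time-varying drift falls back on numerical ODE integration.
#'
#' @param A drift matrix: a `p x p` numeric matrix, or a function of `t`
#'   returning one.  A scalar is accepted when `p = 1`.
#' @param B dispersion matrix: a `p x q` numeric matrix or function of `t`.
#'   The instantaneous noise covariance is `B(t) %*% t(B(t))`.
#' @param a drift offset: a `p`-vector or function of `t`; defaults to zero.
#' @param init_mean mean of the initial condition (`p`-vector).
#' @param init_cov covariance of the initial condition, a symmetric positive
#'   semidefinite `p x p` matrix; the default (zero) is a constant initial
#'   condition.
#' @param t0 initial time.
#'
#' @return An object of class `sde_spec`: a list with elements `p`, `q`,
#'   `A`, `a`, `B` (functions of time), `constant` (are all three
#'   coefficients time-invariant?), `init_mean`, `init_cov` and `t0`.
#' @seealso [ou_spec()] for the Ornstein-Uhlenbeck special case,
#'   [stacked_moments()], [simulate_paths()].
#' @examples
#' # 1-d Brownian motion with drift 0.2 started at 0
#' sp <- sde_spec(A = 0, B = 1, a = 0.2, init_mean = 0)
#' sde_mean(sp, 5)   # 1
#' sde_cov(sp, 5, 5) # 5
#' @export
sde_spec <- function(A, B, a = NULL, init_mean, init_cov = NULL, t0 = 0) {
  init_mean <- as.numeric(init_mean)
  p <- length(init_mean)
  if (p < 1L) stop("'init_mean' must have positive length")
  if (is.null(init_cov)) init_cov <- matrix(0, p, p)
  init_cov <- as.matrix(init_cov)
  if (!identical(dim(init_cov), c(p, p)) && !all(dim(init_cov) == p))
    stop("'init_cov' must be ", p, " x ", p)
  if (max(abs(init_cov - t(init_cov))) > 1e-12 * max(1, max(abs(init_cov))))
    stop("'init_cov' must be symmetric")
  if (min(eigen(init_cov, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-10 * max(1, max(abs(init_cov))))
    stop("'init_cov' must be positive semidefinite")
  if (is.null(a)) a <- rep(0, p)

  Af <- coef_fun(A, p, p, "A")
  af <- coef_fun(a, p, 1L, "a")
  q <- if (is.function(B)) ncol(as.matrix(B(t0))) else ncol(as.matrix(B))
  if (is.null(q) || q < 1L) stop("'B' must have at least one column")
  Bf <- coef_fun(B, p, q, "B")

  spec <- structure(
    list(p = p, q = q,
         A = Af$fun, a = af$fun, B = Bf$fun,
         constant = Af$constant && af$constant && Bf$constant,
         A_constant = Af$constant,
         init_mean = init_mean, init_cov = init_cov, t0 = t0),
    class = "sde_spec")
  check_coef_finite(spec, t0)
  spec
}

# Wrap a constant or time-dependent coefficient as a function of t,
# validating dimensions at t0-like evaluation.
coef_fun <- function(x, nrow, ncol, name) {
  if (is.function(x)) {
    fun <- function(t) {
      v <- as.matrix(x(t))
      if (length(v) == nrow * ncol) dim(v) <- c(nrow, ncol)
      if (!all(dim(v) == c(nrow, ncol)))
        stop("'", name, "(t)' must evaluate to a ", nrow, " x ", ncol,
             " matrix")
      v
    }
    list(fun = fun, constant = FALSE)
  } else {
    v <- as.matrix(x)
    if (length(v) == nrow * ncol) dim(v) <- c(nrow, ncol)
    if (!all(dim(v) == c(nrow, ncol)))
      stop("'", name, "' must be ", nrow, " x ", ncol)
    if (!all(is.finite(v))) stop("'", name, "' has non-finite entries")
    force(v)
    list(fun = function(t) v, constant = TRUE)
  }
}

check_coef_finite <- function(spec, t) {
  for (nm in c("A", "a", "B")) {
    v <- spec[[nm]](t)
    if (!all(is.finite(v)))
      stop("coefficient '", nm, "' is non-finite at t = ", t)
  }
  invisible(TRUE)
}

#' Ornstein-Uhlenbeck trait-evolution specification
#'
#' The mean-reverting process
#' \deqn{dX_t = -\beta (X_t - \theta)\,dt + \sigma\,dW_t, \qquad
#'       X_0 = X_a,}
#' used as a model of quantitative-trait evolution: \eqn{\theta} is the
#' primary (optimal) trait value, \eqn{\beta} the rate of adaptation towards
#' it, \eqn{\sigma} the perturbation from random selective factors, and
#' \eqn{X_a} the ancestral state.  This is the linear SDE with
#' \eqn{A \equiv -\beta}, \eqn{a \equiv \beta\theta}, \eqn{B \equiv \sigma}
#' and a constant initial condition.
#'
#' @param beta adaptation rate (\eqn{\ge 0}); `beta = 0` gives Brownian
#'   motion about the ancestral state.
#' @param theta trait optimum.
#' @param sigma perturbation intensity (\eqn{\ge 0}).
#' @param xa ancestral state (initial value).
#' @param t0 initial time.
#' @return An [sde_spec()] object with `p = q = 1`.
#' @examples
#' sp <- ou_spec(beta = 0.1, theta = 80, sigma = 1, xa = 1)
#' sde_mean(sp, 30)          # 80 + (1 - 80) * exp(-3)
#' sde_cov(sp, 30, 30)       # (1 / 0.2) * (1 - exp(-6))
#' @export
ou_spec <- function(beta, theta, sigma, xa, t0 = 0) {
  stopifnot(length(beta) == 1L, length(theta) == 1L, length(sigma) == 1L,
            length(xa) == 1L)
  if (beta < 0) stop("'beta' must be nonnegative")
  if (sigma < 0) stop("'sigma' must be nonnegative")
  sde_spec(A = matrix(-beta), B = matrix(sigma), a = beta * theta,
           init_mean = xa, t0 = t0)
}

#' @export
print.sde_spec <- function(x, ...) {
  cat("Linear SDE specification\n")
  cat(sprintf("  state dimension p = %d, Wiener dimension q = %d, t0 = %g\n",
              x$p, x$q, x$t0))
  cat(sprintf("  coefficients: %s\n",
              if (x$constant) "time-constant" else "time-varying"))
  cat("  E[X_t0] =", format(x$init_mean, digits = 4), "\n")
  if (any(x$init_cov != 0)) {
    cat("  Gaussian initial condition, Var[X_t0]:\n")
    print(x$init_cov)
  } else {
    cat("  constant initial condition\n")
  }
  invisible(x)
}

#' Observation time vector
#'
#' The common, strictly increasing vector of \eqn{N} time points at which
#' every training and test sample path is observed.  A path observed on the
#' grid is stacked into one \eqn{Np}-dimensional feature vector, which is
#' the space in which all classifiers of this package operate.
#'
#' @param times strictly increasing numeric vector of observation times.
#' @param p state dimension of the process observed on the grid.
#' @return An object of class `obs_grid` with elements `times`, `p`, `N`
#'   (number of time points) and `dim` (= `N * p`, the stacked dimension).
#' @examples
#' g <- obs_grid(1:20, p = 3)
#' g$dim  # 60
#' @export
obs_grid <- function(times, p = 1L) {
  times <- as.numeric(times)
  if (length(times) < 1L) stop("'times' must be nonempty")
  if (!all(is.finite(times))) stop("'times' must be finite")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  p <- as.integer(p)
  if (p < 1L) stop("'p' must be a positive integer")
  structure(list(times = times, p = p, N = length(times),
                 dim = length(times) * p),
            class = "obs_grid")
}

#' @export
print.obs_grid <- function(x, ...) {
  cat(sprintf("Observation grid: N = %d times in [%g, %g], p = %d (stacked dimension %d)\n",
              x$N, x$times[1L], x$times[x$N], x$p, x$dim))
  invisible(x)
}

# Grid/spec compatibility: all observation times at or after t0.
check_grid_spec <- function(grid, spec) {
  stopifnot(inherits(grid, "obs_grid"), inherits(spec, "sde_spec"))
  if (grid$p != spec$p)
    stop("grid has p = ", grid$p, " but spec has p = ", spec$p)
  if (grid$times[1L] < spec$t0)
    stop("observation times must not precede the spec's t0 = ", spec$t0)
  invisible(TRUE)
}
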