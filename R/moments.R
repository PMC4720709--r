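#' Fundamental matrix of the homogeneous drift system
#'
#' Returns \eqn{\Phi(t)} solving \eqn{d\Phi/dt = A(t)\Phi},
#' \eqn{\Phi(t_0) = I}.  For a time-constant drift matrix this is the matrix
#' exponential \eqn{e^{A (t - t_0)}}; for time-varying \eqn{A(t)} the system
#' is integrated numerically (no commutativity assumption is made, so the
#' exponential of \eqn{\int A} is deliberately not used).
#'
#' @param spec an [sde_spec()].
#' @param t evaluation time, `t >= spec$t0`.
#' @return A `p x p` matrix.
#' @examples
#' sp <- sde_spec(A = diag(0.01, 3), B = diag(3), init_mean = rep(0, 3))
#' fundamental_matrix(sp, 1)  # diag(exp(0.01), 3)
#' @export
fundamental_matrix <- function(spec, t) {
  stopifnot(inherits(spec, "sde_spec"), length(t) == 1L, is.finite(t))
  if (t < spec$t0) stop("'t' must be >= spec$t0")
  matrix(phi_at(spec, t)[, , 1L], spec$p, spec$p)
}

# Fundamental matrices at a vector of times >= t0, as a p x p x K array.
# Constant A: matrix exponential per time.  Time-varying A: one ODE solve
# over the sorted times with tight tolerances, integrating all p columns of
# Phi simultaneously.
phi_at <- function(spec, times) {
  p <- spec$p
  K <- length(times)
  out <- array(0, dim = c(p, p, K))
  if (spec$A_constant) {
    A <- spec$A(spec$t0)
    if (!all(is.finite(A))) stop("drift matrix 'A' has non-finite entries")
    for (k in seq_len(K))
      out[, , k] <- as.matrix(Matrix::expm(A * (times[k] - spec$t0)))
    return(out)
  }
  ord <- order(times)
  st <- times[ord]
  ut <- unique(st)
  tt <- ut
  if (tt[1L] > spec$t0) tt <- c(spec$t0, tt)
  deriv <- function(t, y, parms) {
    A <- spec$A(t)
    if (!all(is.finite(A)))
      stop("drift matrix 'A' is non-finite at t = ", t)
    list(as.vector(A %*% matrix(y, p, p)))
  }
  sol <- deSolve::ode(y = as.vector(diag(p)), times = tt, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-12)
  idx <- match(ut, tt)
  phis <- array(t(sol[idx, -1L, drop = FALSE]), dim = c(p, p, length(ut)))
  for (k in seq_len(K))
    out[, , k] <- phis[, , match(times[k], ut)]
  out
}

# Gauss-Legendre quadrature of the moment integrals on the intervals
# [t0, t_1], [t_1, t_2], ..., returning cumulative integrals at the grid
# times:
#   Ja(t_k) = int_{t0}^{t_k} Phi(s)^{-1} a(s) ds                (p-vector)
#   JB(t_k) = int_{t0}^{t_k} Phi(u)^{-1} B B' Phi(u)^{-T} du    (p x p)
# together with Phi at the grid times.  `nq` nodes per interval.
moment_engine <- function(spec, times, nq) {
  p <- spec$p
  K <- length(times)
  breaks <- c(spec$t0, times)
  nodes <- numeric(0)
  weights <- numeric(0)
  seg <- integer(0)
  for (k in seq_len(K)) {
    lo <- breaks[k]; hi <- breaks[k + 1L]
    if (hi > lo) {
      gl <- pracma::gaussLegendre(nq, lo, hi)
      nodes <- c(nodes, gl$x)
      weights <- c(weights, gl$w)
      seg <- c(seg, rep.int(k, nq))
    }
  }
  phis_grid <- phi_at(spec, times)
  Ja <- matrix(0, p, K)
  JB <- array(0, dim = c(p, p, K))
  if (length(nodes)) {
    phis_nodes <- phi_at(spec, nodes)
    ja_acc <- numeric(p)
    jb_acc <- matrix(0, p, p)
    i <- 1L
    for (k in seq_len(K)) {
      while (i <= length(nodes) && seg[i] == k) {
        s <- nodes[i]
        Minv <- tryCatch(solve(phis_nodes[, , i]), error = function(e)
          stop("fundamental matrix is numerically singular at t = ", s,
               "; the drift specification is likely invalid", call. = FALSE))
        av <- spec$a(s)
        if (!all(is.finite(av)))
          stop("drift offset 'a' is non-finite at t = ", s)
        Bv <- spec$B(s)
        if (!all(is.finite(Bv)))
          stop("dispersion 'B' is non-finite at t = ", s)
        MB <- Minv %*% Bv
        ja_acc <- ja_acc + weights[i] * as.vector(Minv %*% av)
        jb_acc <- jb_acc + weights[i] * tcrossprod(MB)
        i <- i + 1L
      }
      Ja[, k] <- ja_acc
      JB[, , k] <- jb_acc
    }
  }
  list(times = times, phis = phis_grid, Ja = Ja, JB = JB)
}

# Run the engine with nq and 2*nq nodes per interval, doubling until the
# stacked mean and covariance agree to `tol` relative, so that the
# quadrature error is negligible against every tolerance used downstream.
moment_engine_adaptive <- function(spec, times, nq = 16L, tol = 1e-9,
                                   max_nq = 256L) {
  cur <- moment_engine(spec, times, nq)
  repeat {
    nq2 <- 2L * nq
    fine <- moment_engine(spec, times, nq2)
    sc <- max(1, max(abs(fine$Ja)), max(abs(fine$JB)))
    err <- max(max(abs(fine$Ja - cur$Ja)), max(abs(fine$JB - cur$JB))) / sc
    if (err < tol || nq2 >= max_nq) return(fine)
    nq <- nq2
    cur <- fine
  }
}

moments_from_engine <- function(spec, eng) {
  p <- spec$p
  K <- length(eng$times)
  means <- matrix(0, p, K)
  for (k in seq_len(K))
    means[, k] <- eng$phis[, , k] %*% (spec$init_mean + eng$Ja[, k])
  means
}

#' Mean function of a linear SDE
#'
#' Closed-form mean
#' \eqn{m_t = \Phi(t)\,(E[c] + \int_{t_0}^{t} \Phi(s)^{-1} a(s)\,ds)}
#' of the Gaussian process solving the linear SDE, with the integral
#' evaluated by composite Gauss-Legendre quadrature refined until
#' convergence.
#'
#' @inheritParams fundamental_matrix
#' @return A `p`-vector.
#' @export
sde_mean <- function(spec, t) {
  stopifnot(inherits(spec, "sde_spec"), length(t) == 1L, is.finite(t))
  if (t < spec$t0) stop("'t' must be >= spec$t0")
  eng <- moment_engine_adaptive(spec, t)
  as.vector(moments_from_engine(spec, eng))
}

#' Covariance function of a linear SDE
#'
#' Closed-form auto-covariance
#' \deqn{\Psi_{t_i,t_j} = \Phi(t_i)\Big(\mathrm{Var}[c] +
#'   \int_{t_0}^{\min(t_i,t_j)} \Phi(u)^{-1} B(u) B(u)^T
#'   (\Phi(u)^{-1})^T du\Big)\,\Phi(t_j)^T}
#' of the Gaussian process solving the linear SDE.  For \eqn{t_i > t_j} the
#' result is the transpose of the \eqn{(t_j, t_i)} block, which the function
#' returns directly.
#'
#' @inheritParams fundamental_matrix
#' @param ti,tj evaluation times, both `>= spec$t0`.
#' @return A `p x p` matrix.
#' @export
sde_cov <- function(spec, ti, tj) {
  stopifnot(inherits(spec, "sde_spec"),
            length(ti) == 1L, length(tj) == 1L,
            is.finite(ti), is.finite(tj))
  if (ti < spec$t0 || tj < spec$t0) stop("'ti', 'tj' must be >= spec$t0")
  ts <- sort(unique(c(ti, tj)))
  eng <- moment_engine_adaptive(spec, ts)
  i <- match(ti, ts); j <- match(tj, ts)
  m <- min(i, j)
  eng$phis[, , i] %*% (spec$init_cov + eng$JB[, , m]) %*% t(eng$phis[, , j])
}

#' Stacked moments of a linear SDE on an observation grid
#'
#' Assembles the mean vector and block covariance matrix of the
#' \eqn{Np}-dimensional stacked observation
#' \eqn{[X_{t_1}^T, \ldots, X_{t_N}^T]^T} of the process on the grid, using
#' the closed-form moment functions.  Blocks are ordered by time index,
#' each block `p x p`; the covariance is symmetrized exactly.
#'
#' @inheritParams fundamental_matrix
#' @param grid an [obs_grid()] compatible with `spec`.
#' @return A list with elements `mean` (length `grid$dim`) and `cov`
#'   (`grid$dim x grid$dim`, symmetric).
#' @examples
#' sp <- ou_spec(0.1, 80, 1, 1)
#' mom <- stacked_moments(sp, obs_grid(1:5))
#' mom$mean
#' @export
stacked_moments <- function(spec, grid) {
  check_grid_spec(grid, spec)
  p <- spec$p; N <- grid$N
  eng <- moment_engine_adaptive(spec, grid$times)
  means <- moments_from_engine(spec, eng)
  m <- as.vector(means)
  S <- matrix(0, N * p, N * p)
  # column factors C_k = Var[c] + JB(t_k); block (i,j) with i <= j is
  # Phi(t_i) C_i Phi(t_j)^T
  for (i in seq_len(N)) {
    Ci <- spec$init_cov + eng$JB[, , i]
    Pi <- eng$phis[, , i]
    rows <- ((i - 1L) * p + 1L):(i * p)
    for (j in i:N) {
      cols <- ((j - 1L) * p + 1L):(j * p)
      blk <- Pi %*% Ci %*% t(eng$phis[, , j])
      S[rows, cols] <- blk
      if (j > i) S[cols, rows] <- t(blk)
    }
  }
  S <- (S + t(S)) / 2
  list(mean = m, cov = S)
}
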