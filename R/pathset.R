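#' Labeled set of sample paths on a common observation grid
#'
#' Container for `n` sample paths of a `p`-dimensional process observed at
#' the `N` times of a shared [obs_grid()].  For classification each path is
#' stacked into one `N * p`-dimensional vector (time-major: the `p`-vector
#' at \eqn{t_1} first).  Test paths whose class is unknown carry the
#' sentinel label `NA`.
#'
#' @param paths an `n x N x p` numeric array, or an `n x N` matrix when
#'   `p = 1`.
#' @param grid the [obs_grid()] the paths were observed on.
#' @param label class label in `{0, 1}`, or `NA` for unlabeled paths.
#' @return An object of class `pathset` with elements `paths`, `grid`,
#'   `label` and `n`.
#' @export
pathset <- function(paths, grid, label = NA_integer_) {
  stopifnot(inherits(grid, "obs_grid"))
  if (is.matrix(paths) && grid$p == 1L)
    paths <- array(paths, dim = c(nrow(paths), ncol(paths), 1L))
  if (!is.array(paths) || length(dim(paths)) != 3L)
    stop("'paths' must be an n x N x p array")
  d <- dim(paths)
  if (d[2L] != grid$N || d[3L] != grid$p)
    stop("'paths' must be n x ", grid$N, " x ", grid$p,
         " to match the grid")
  if (d[1L] < 1L) stop("a pathset must contain at least one path")
  if (!all(is.finite(paths))) stop("'paths' contains non-finite values")
  if (!is.na(label) && !label %in% c(0, 1))
    stop("'label' must be 0, 1 or NA")
  structure(list(paths = paths, grid = grid,
                 label = if (is.na(label)) NA_integer_ else as.integer(label),
                 n = d[1L]),
            class = "pathset")
}

#' @export
print.pathset <- function(x, ...) {
  cat(sprintf("Path set: %d sample path%s, N = %d times, p = %d (label: %s)\n",
              x$n, if (x$n == 1L) "" else "s", x$grid$N, x$grid$p,
              if (is.na(x$label)) "unlabeled" else x$label))
  invisible(x)
}

#' Stack sample paths into feature vectors
#'
#' Concatenates the `p`-vectors observed at \eqn{t_1, \ldots, t_N} in time
#' order into a single `N * p` feature vector, matching the block order of
#' the stacked moments.  Applied to a path set (or `n x N x p` array) it
#' returns the `n x (N * p)` matrix of stacked observations; applied to a
#' single `N x p` path it returns one vector.
#'
#' @param x a [pathset()], an `n x N x p` array, or a single `N x p`
#'   matrix.
#' @return A numeric matrix (rows = paths) or vector.
#' @examples
#' stack_paths(matrix(c(3, 7), nrow = 2))  # c(3, 7)
#' @export
stack_paths <- function(x) {
  if (inherits(x, "pathset")) x <- x$paths
  if (is.matrix(x)) {
    if (!all(is.finite(x))) stop("path contains non-finite values")
    return(as.vector(t(x)))
  }
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("'x' must be a pathset, an n x N x p array or an N x p matrix")
  d <- dim(x)
  out <- matrix(0, d[1L], d[2L] * d[3L])
  for (j in seq_len(d[2L]))
    out[, ((j - 1L) * d[3L] + 1L):(j * d[3L])] <- x[, j, ]
  out
}

#' Unstack a feature vector into an N x p path
#'
#' Inverse of [stack_paths()] for a single observation.
#'
#' @param v a stacked vector of length `grid$dim`.
#' @param grid the [obs_grid()] defining `N` and `p`.
#' @return An `N x p` matrix.
#' @export
unstack_path <- function(v, grid) {
  stopifnot(inherits(grid, "obs_grid"))
  if (length(v) != grid$dim)
    stop("'v' must have length ", grid$dim)
  matrix(v, nrow = grid$N, ncol = grid$p, byrow = TRUE)
}

#' Sample mean and covariance of stacked observations
#'
#' The sample mean and unbiased (divisor `n - 1`) sample covariance of the
#' stacked `N * p`-dimensional observations of a path set.
#'
#' @param x a [pathset()] or a numeric matrix whose rows are stacked
#'   observations.
#' @return A list with elements `mean` (vector), `cov` (symmetric matrix)
#'   and `n`.
#' @examples
#' g <- obs_grid(1)
#' ps <- pathset(array(c(0, 2), dim = c(2, 1, 1)), g)
#' empirical_moments(ps)  # mean 1, cov 2
#' @export
empirical_moments <- function(x) {
  X <- if (inherits(x, "pathset")) stack_paths(x) else as.matrix(x)
  n <- nrow(X)
  if (n < 2L)
    stop("at least two paths are needed for a sample covariance (n = ",
         n, ")")
  S <- stats::cov(X)
  list(mean = colMeans(X), cov = (S + t(S)) / 2, n = n)
}

#' Monte-Carlo moment estimate from simulated SDE paths
#'
#' Simulates `l` sample paths of the SDE on the grid and returns their
#' sample mean and covariance.  This is the simulation route to the stacked
#' moments: as `l` grows the estimates converge to the closed forms of
#' [stacked_moments()], and with `l > N * p` the sample covariance is
#' almost surely positive definite.
#'
#' @inheritParams simulate_paths
#' @param l number of simulated paths (`>= 2`; take `l` much larger than
#'   `N * p` for a well-conditioned covariance).
#' @return A list with elements `mean`, `cov` and `n` (= `l`).
#' @export
sde_moment_estimate <- function(spec, grid, l, seed = NULL, substeps = 10L) {
  l <- as.integer(l)
  if (l < 2L) stop("'l' must be >= 2")
  empirical_moments(simulate_paths(spec, grid, n = l, substeps = substeps,
                                   seed = seed))
}
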