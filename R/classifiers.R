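# Discriminants over stacked Np-dimensional observations: stochastic QDA,
# the optimal Bayesian classifier (OBC), and the plug-in Bayes rule.
#
# All quadratic forms and log-determinants go through one Cholesky
# factorization per class; explicit matrix inverses are never formed.

# Gaussian class bundle: mean, covariance, upper Cholesky factor, log|Psi|.
gauss_bundle <- function(m, Psi, what = "covariance") {
  m <- as.numeric(m)
  Psi <- as.matrix(Psi)
  Psi <- (Psi + t(Psi)) / 2
  R <- tryCatch(chol(Psi), error = function(e)
    stop("class ", what, " matrix is not positive definite", call. = FALSE))
  list(m = m, Psi = Psi, R = R, logdet = 2 * sum(log(diag(R))))
}

# Quadratic forms (x - m)' Psi^{-1} (x - m) for rows of X, via the stored
# Cholesky factor.
qforms <- function(bundle, X) {
  Xc <- sweep(X, 2L, bundle$m)
  Z <- backsolve(bundle$R, t(Xc), transpose = TRUE)
  colSums(Z^2)
}

# Coerce classifier input (pathset, stacked matrix, or single vector) to a
# matrix of stacked observations.
as_stacked <- function(x, d) {
  X <- if (inherits(x, "pathset")) stack_paths(x)
       else if (is.matrix(x)) x
       else matrix(as.numeric(x), nrow = 1L)
  if (ncol(X) != d)
    stop("observations have dimension ", ncol(X),
         " but the classifier expects ", d)
  X
}

new_gp_classifier <- function(kind, class0, class1, alpha1, d, extra = NULL) {
  if (!(alpha1 > 0 && alpha1 < 1))
    stop("'alpha1' must lie strictly between 0 and 1")
  structure(c(list(kind = kind, class0 = class0, class1 = class1,
                   alpha1 = alpha1, d = d), extra),
            class = "gp_classifier")
}

#' Stochastic QDA from per-class Gaussian moments
#'
#' Builds the quadratic discriminant from explicit class means and
#' covariances of the stacked observation.  [build_qda_from_data()] and
#' [build_qda_from_sde()] are the usual entry points; this constructor is
#' exposed for moments obtained elsewhere.
#'
#' @param m0,m1 class mean vectors (length `d`).
#' @param Psi0,Psi1 symmetric positive definite `d x d` class
#'   covariances.
#' @param alpha1 class-1 mixing probability, in (0, 1).  Under separate
#'   (stratified) sampling it must be known a priori; it cannot be
#'   estimated from per-class path counts.
#' @return An object of class `gp_classifier` with `kind = "qda"`.
#' @export
qda_classifier <- function(m0, Psi0, m1, Psi1, alpha1 = 0.5) {
  b0 <- gauss_bundle(m0, Psi0)
  b1 <- gauss_bundle(m1, Psi1)
  if (length(b0$m) != length(b1$m))
    stop("class parameter dimensions disagree")
  new_gp_classifier("qda", b0, b1, alpha1, d = length(b0$m))
}

#' QDA discriminant statistic
#'
#' Evaluates
#' \deqn{\psi(x) = -\tfrac12 (x - m^0)^T \Psi_0^{-1} (x - m^0)
#'   + \tfrac12 (x - m^1)^T \Psi_1^{-1} (x - m^1)
#'   + \tfrac12 \log\frac{|\Psi_1^{-1}|}{|\Psi_0^{-1}|}
#'   - \log\frac{\alpha_1}{1 - \alpha_1},}
#' the log ratio of the two weighted Gaussian class densities; positive
#' values favor class 0.  Log-determinants come from the Cholesky factors
#' stored in the model.
#'
#' @param model a QDA-kind `gp_classifier`.
#' @param x a [pathset()], a matrix of stacked observations (rows), or a
#'   single stacked vector.
#' @return A numeric vector, one statistic per observation.
#' @export
qda_discriminant <- function(model, x) {
  stopifnot(inherits(model, "gp_classifier"))
  if (!model$kind %in% c("qda", "plugin"))
    stop("'model' is not a QDA-kind classifier")
  X <- as_stacked(x, model$d)
  -0.5 * qforms(model$class0, X) + 0.5 * qforms(model$class1, X) +
    0.5 * (model$class0$logdet - model$class1$logdet) -
    log(model$alpha1 / (1 - model$alpha1))
}

#' Log effective class-conditional density of the OBC
#'
#' Under a normal-inverse-Wishart posterior the class-conditional Gaussian
#' density averaged over the posterior of its parameters (the *effective*
#' class-conditional density) is a multivariate Student-t with
#' \eqn{k = \kappa^* - Np + 1} degrees of freedom, location \eqn{m^*} and
#' scale \eqn{\Pi = \frac{\nu^*+1}{(\kappa^*-Np+1)\nu^*}\Psi^*}.  This
#' returns its normalized log density
#' \deqn{\log\Gamma\!\big(\tfrac{k+d}{2}\big) - \log\Gamma\!\big(\tfrac
#'   k2\big) - \tfrac d2 \log(k\pi) - \tfrac12 \log|\Pi|
#'   - \tfrac{k+d}{2}\log\!\Big(1 + \tfrac1k (x-m^*)^T \Pi^{-1}
#'   (x-m^*)\Big).}
#'
#' @param params a list with elements `m` (location), `Pi` (scale matrix)
#'   and `k` (degrees of freedom), e.g. `model$class0` of an OBC
#'   [build_obc()] model.
#' @param x matrix of stacked observations (rows) or a single vector.
#' @return Numeric vector of log densities.
#' @export
obc_log_effective_density <- function(params, x) {
  if (is.null(params$R)) params <- st_bundle(params$m, params$Pi, params$k)
  d <- length(params$m)
  X <- as_stacked(x, d)
  q <- qforms(params, X)
  if (!all(is.finite(q))) stop("non-finite quadratic form")
  lgamma((params$k + d) / 2) - lgamma(params$k / 2) -
    (d / 2) * log(params$k * pi) - 0.5 * params$logdet -
    ((params$k + d) / 2) * log1p(q / params$k)
}

st_bundle <- function(m, Pi, k) {
  if (k <= 0) stop("degrees of freedom must be positive")
  b <- gauss_bundle(m, Pi, what = "scale")
  b$Pi <- b$Psi
  b$k <- k
  b
}

#' Optimal Bayesian classifier from class posteriors
#'
#' Builds the OBC from the two normal-inverse-Wishart posteriors.  Each
#' class's effective class-conditional density is the multivariate
#' Student-t with \eqn{k^y = \kappa^{y*} - Np + 1} degrees of freedom,
#' location \eqn{m^{y*}} and scale
#' \eqn{\Pi^y = \frac{\nu^{y*}+1}{(\kappa^{y*}-Np+1)\nu^{y*}}\Psi^{y*}};
#' a test point is assigned class 0 when
#' \eqn{(1-\alpha_1) f(x \mid 0) \ge \alpha_1 f(x \mid 1)}, evaluated in
#' log space (ties go to class 0).  The log-space comparison is a strictly
#' monotone reformulation of the polynomial-power discriminant and does
#' not overflow at large \eqn{Np}.
#'
#' @param post0,post1 [niw()] posteriors (a prior may be supplied when no
#'   training paths exist, giving the robust no-data classifier).
#' @param alpha1 class-1 mixing probability, known a priori.
#' @return A `gp_classifier` with `kind = "obc"`; `class0`/`class1` hold
#'   `m`, `Pi` and `k` per class.
#' @export
build_obc <- function(post0, post1, alpha1 = 0.5) {
  stopifnot(inherits(post0, "niw"), inherits(post1, "niw"))
  if (post0$d != post1$d) stop("posterior dimensions disagree")
  mk <- function(po) {
    k <- po$kappa - po$d + 1
    if (k <= 0)
      stop("invalid posterior: kappa* - Np + 1 = ", k, " must be positive")
    st_bundle(po$m, ((po$nu + 1) / (k * po$nu)) * po$Psi, k)
  }
  new_gp_classifier("obc", mk(post0), mk(post1), alpha1, d = post0$d)
}

#' QDA / plug-in Bayes classifier from SDE moments
#'
#' Builds the quadratic discriminant whose class parameters are the
#' stacked Gaussian-process moments implied by the two SDE specifications
#' -- no training sample paths are involved.  With the ground-truth
#' specifications this is the (plug-in) Bayes classifier, whose error
#' lower-bounds every classifier on the same problem.  Moments are either
#' the closed forms or Monte-Carlo estimates from `l` simulated paths per
#' class (the latter requires `l > Np` for an invertible covariance).
#'
#' @param spec0,spec1 [sde_spec()] objects for the two classes.
#' @inheritParams prior_from_sde
#' @param alpha1 class-1 mixing probability.
#' @return A `gp_classifier` with `kind = "plugin"`.
#' @export
build_qda_from_sde <- function(spec0, spec1, grid, alpha1 = 0.5,
                               moment_source = c("analytic", "simulated"),
                               l = 2000L, seed = NULL, substeps = 10L) {
  moment_source <- match.arg(moment_source)
  get_mom <- function(spec, which) {
    if (moment_source == "analytic") return(stacked_moments(spec, grid))
    if (l <= grid$dim)
      stop("'l' must exceed Np = ", grid$dim,
           " for an invertible simulated covariance")
    sde_moment_estimate(spec, grid, l = l, substeps = substeps,
                        seed = if (is.null(seed)) NULL
                               else derive_seed(seed, "plugin", which))
  }
  mom0 <- get_mom(spec0, 0L)
  mom1 <- get_mom(spec1, 1L)
  cl <- qda_classifier(mom0$mean, mom0$cov, mom1$mean, mom1$cov, alpha1)
  cl$kind <- "plugin"
  cl
}

#' Stochastic QDA trained on sample paths
#'
#' Plugs the per-class sample means and covariances of the stacked
#' training paths into the quadratic discriminant.  The sample covariances
#' are invertible only when each class has more training paths than the
#' stacked dimension, so `min(n0, n1) > Np` is required.
#'
#' @param train0,train1 labeled [pathset()]s for classes 0 and 1 on a
#'   common grid.
#' @param alpha1 class-1 mixing probability.
#' @return A `gp_classifier` with `kind = "qda"`.
#' @export
build_qda_from_data <- function(train0, train1, alpha1 = 0.5) {
  stopifnot(inherits(train0, "pathset"), inherits(train1, "pathset"))
  d <- train0$grid$dim
  if (train1$grid$dim != d)
    stop("training path sets live on grids of different stacked dimension")
  nmin <- min(train0$n, train1$n)
  if (nmin <= d)
    stop("QDA needs min(n0, n1) > Np = ", d,
         " training paths per class for invertible sample covariances; ",
         "got min = ", nmin,
         ". Use the OBC (with an SDE prior) for smaller samples.")
  e0 <- empirical_moments(train0)
  e1 <- empirical_moments(train1)
  qda_classifier(e0$mean, e0$cov, e1$mean, e1$cov, alpha1)
}

#' Classify stacked observations or sample paths
#'
#' For QDA-kind models, class 0 is assigned iff the discriminant is
#' strictly positive.  For the OBC, class 0 is assigned iff
#' \eqn{\log(1-\alpha_1) + \log f(x\mid 0) \ge \log\alpha_1 +
#' \log f(x\mid 1)}; exact ties go to class 0.
#'
#' @param object a `gp_classifier`.
#' @param newdata a [pathset()], matrix of stacked observations (rows), or
#'   a single stacked vector.
#' @param type `"class"` for hard labels, `"score"` for the decision
#'   statistic (log odds in favor of class 0).
#' @param ... unused.
#' @return Integer labels in `{0, 1}` or numeric scores.
#' @export
predict.gp_classifier <- function(object, newdata,
                                  type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as_stacked(newdata, object$d)
  if (object$kind %in% c("qda", "plugin")) {
    s <- qda_discriminant(object, X)
    if (type == "score") return(s)
    return(ifelse(s > 0, 0L, 1L))
  }
  s <- log1p(-object$alpha1) + obc_log_effective_density(object$class0, X) -
    log(object$alpha1) - obc_log_effective_density(object$class1, X)
  if (type == "score") s else ifelse(s >= 0, 0L, 1L)
}

#' @export
print.gp_classifier <- function(x, ...) {
  kind <- switch(x$kind, obc = "optimal Bayesian classifier (OBC)",
                 qda = "stochastic QDA", plugin = "plug-in Bayes (QDA form)")
  cat(sprintf("Gaussian-process classifier: %s\n", kind))
  cat(sprintf("  stacked dimension Np = %d, alpha1 = %g\n", x$d, x$alpha1))
  if (x$kind == "obc")
    cat(sprintf("  effective densities: multivariate t, dof k0 = %g, k1 = %g\n",
                x$class0$k, x$class1$k))
  invisible(x)
}

#' @export
summary.gp_classifier <- function(object, ...) {
  print(object)
  for (y in 0:1) {
    b <- object[[paste0("class", y)]]
    cat(sprintf("  class %d: |mean| range [%.4g, %.4g], %s log-det = %.4g, cond = %.3g\n",
                y, min(b$m), max(b$m),
                if (is.null(b$Pi)) "covariance" else "scale",
                b$logdet, kappa(b$R, exact = FALSE)))
  }
  invisible(object)
}

#' @export
coef.gp_classifier <- function(object, ...) {
  list(kind = object$kind, alpha1 = object$alpha1,
       class0 = object$class0[intersect(names(object$class0),
                                        c("m", "Psi", "Pi", "k"))],
       class1 = object$class1[intersect(names(object$class1),
                                        c("m", "Psi", "Pi", "k"))])
}
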