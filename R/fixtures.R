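# Named ground-truth experiment configurations.

#' Named ground-truth experiment fixtures
#'
#' Returns the fully instantiated pair of class-conditional SDE
#' specifications, the observation grid and the default study parameters
#' for one of the built-in experiments:
#'
#' * `"eq33"` -- the three-dimensional drift/dispersion study: both classes
#'   share drift matrix `diag(0.01, 3)`, zero drift offset, and dispersion
#'   `B = 0.1 * M` where `M` has unit diagonal and off-diagonal entries
#'   `rho = 0.4`; the classes differ only in their constant initial
#'   conditions (`c(0,0,0)` vs `c(0.25,0.25,0.25)`).  Grid: `N = 20`
#'   unit-spaced times `1..20`, so `Np = 60`.
#' * `"ou_beta010"`, `"ou_beta015"` -- the quantitative-trait evolution
#'   study: both species follow the Ornstein-Uhlenbeck model
#'   [ou_spec()] with `sigma = 1` and common ancestral state `xa = 1`,
#'   trait optima `theta0 = 80` vs `theta1 = 85`, and adaptation rate
#'   `beta = 0.1` or `0.15`.  Grid: 30 time steps of one unit (millions of
#'   years), so `Np = 30`.
#'
#' @param name fixture name.
#' @param overrides named list replacing individual parameters (e.g.
#'   `list(rho = 0.2)` or `list(theta1 = 90)`); unnamed parameters keep
#'   their fixture values.
#' @return A list with elements `name`, `params`, `spec0`, `spec1`,
#'   `grid`, `Np`, and experiment defaults `alpha1`, `substeps`, `n`
#'   (training-size grid), `kappa` (offsets added to `Np` for the
#'   hyperparameters), `n_test`, `reps`, `l`.
#' @export
make_fixture <- function(name = c("eq33", "ou_beta010", "ou_beta015"),
                         overrides = list()) {
  name <- match.arg(name)
  stopifnot(is.list(overrides))
  if (name == "eq33") {
    par <- list(drift = 0.01, sigma2 = 1, rho = 0.4, scale = 0.1,
                init0 = c(0, 0, 0), init1 = c(0.25, 0.25, 0.25),
                t0 = 0, N = 20L, dt = 1)
    par <- utils::modifyList(par, overrides)
    B <- eq33_dispersion(par)
    A <- diag(par$drift, 3)
    grid <- obs_grid(par$t0 + par$dt * seq_len(par$N), p = 3L)
    spec0 <- sde_spec(A = A, B = B, init_mean = par$init0, t0 = par$t0)
    spec1 <- sde_spec(A = A, B = B, init_mean = par$init1, t0 = par$t0)
    defaults <- list(n = c(65L, 80L, 100L, 120L))
  } else {
    par <- list(beta = if (name == "ou_beta010") 0.1 else 0.15,
                theta0 = 80, theta1 = 85, sigma = 1, xa = 1,
                t0 = 0, N = 30L, dt = 1)
    par <- utils::modifyList(par, overrides)
    grid <- obs_grid(par$t0 + par$dt * seq_len(par$N), p = 1L)
    spec0 <- ou_spec(par$beta, par$theta0, par$sigma, par$xa, t0 = par$t0)
    spec1 <- ou_spec(par$beta, par$theta1, par$sigma, par$xa, t0 = par$t0)
    defaults <- list(n = c(60L, 100L, 140L))
  }
  c(list(name = name, params = par, spec0 = spec0, spec1 = spec1,
         grid = grid, Np = grid$dim,
         alpha1 = 0.5, substeps = 10L,
         kappa = c(20, 50, 100, 500), n_test = 500L, reps = 50L,
         l = 2000L),
    defaults)
}

eq33_dispersion <- function(par) {
  M <- matrix(par$rho, 3, 3)
  diag(M) <- par$sigma2
  par$scale * M
}

# A-priori (possibly misspecified) spec pair for a fixture and one offset.
#   dmu:   added to each diagonal entry of the class-1 drift matrix
#   drho:  added to the off-diagonal correlation rho before the 0.1 scaling
#   dbeta: added to the class-1 adaptation rate
apriori_specs <- function(fixture, offset_name, offset_value) {
  par <- fixture$params
  switch(offset_name,
    none = list(spec0 = fixture$spec0, spec1 = fixture$spec1),
    dmu = {
      stopifnot(fixture$name == "eq33")
      A1 <- diag(par$drift + offset_value, 3)
      list(spec0 = fixture$spec0,
           spec1 = sde_spec(A = A1, B = eq33_dispersion(par),
                            init_mean = par$init1, t0 = par$t0))
    },
    drho = {
      stopifnot(fixture$name == "eq33")
      par1 <- par; par1$rho <- par$rho + offset_value
      list(spec0 = fixture$spec0,
           spec1 = sde_spec(A = diag(par$drift, 3),
                            B = eq33_dispersion(par1),
                            init_mean = par$init1, t0 = par$t0))
    },
    dbeta = {
      stopifnot(fixture$name != "eq33")
      list(spec0 = fixture$spec0,
           spec1 = ou_spec(par$beta + offset_value, par$theta1, par$sigma,
                           par$xa, t0 = par$t0))
    },
    stop("unknown offset name: ", offset_name))
}
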