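# True-error estimation and the misspecification experiment protocols.

#' Monte-Carlo true error of a classifier
#'
#' Estimates the probability of misclassification
#' \eqn{\epsilon = (1-\alpha_1) P(\psi(X) = 1 \mid Y = 0) +
#'      \alpha_1 P(\psi(X) = 0 \mid Y = 1)}
#' from held-out test path sets, one per class.  Under separate sampling
#' the mixing probability `alpha1` must be known a priori; it defaults to
#' the one stored in the model.
#'
#' @param model a `gp_classifier`.
#' @param test0,test1 test [pathset()]s drawn from the class-0 and
#'   class-1 processes, observed on the model's grid.
#' @param alpha1 class-1 mixing probability.
#' @return Error estimate in `[0, 1]`.
#' @export
true_error <- function(model, test0, test1, alpha1 = model$alpha1) {
  stopifnot(inherits(model, "gp_classifier"))
  p0 <- predict(model, test0)
  p1 <- predict(model, test1)
  (1 - alpha1) * mean(p0 == 1L) + alpha1 * mean(p1 == 0L)
}

#' Experiment configuration
#'
#' Bundles the knobs of the misspecification study: which fixture supplies
#' the ground truth, which offset distorts the a-priori class-1 SDE, and
#' the sweep over training sizes and prior strengths.  The defaults are
#' the reduced-scale profile (`reps = 50` replicates, `n_test = 500` test
#' paths per class); the full-scale study (`reps = 1000`,
#' `n_test = 2000`) is obtained by overriding those two numbers.
#'
#' Hyperparameters follow the rule `nu = kappa = Np + kappa_offset` for
#' both classes, and priors are matched to the a-priori SDE moments via
#' [prior_from_sde()].
#'
#' @param fixture fixture name, see [make_fixture()].
#' @param offset_name one of `"none"`, `"dmu"` (drift-diagonal shift,
#'   `eq33`), `"drho"` (dispersion-correlation shift, `eq33`), `"dbeta"`
#'   (adaptation-rate shift, OU fixtures).
#' @param offset_values numeric vector of offsets applied to the a-priori
#'   class-1 SDE.
#' @param n training sizes per class; every value must exceed `Np` so the
#'   data-driven QDA is defined.  Defaults to the fixture's grid.
#' @param kappa offsets added to `Np` to form `nu = kappa`; defaults to
#'   the fixture's `c(20, 50, 100, 500)`.
#' @param n_test test paths per class per replicate.
#' @param reps number of replicates `T`.
#' @param l simulated paths for the plug-in Bayes reference (and for
#'   prior moments when `prior_moments = "simulated"`).
#' @param prior_moments `"analytic"` (closed-form SDE moments, default) or
#'   `"simulated"` (`l` paths per class).
#' @param alpha1 class-1 mixing probability (stratified sampling).
#' @param substeps Euler-Maruyama substeps per unit interval.
#' @param seed root seed; every randomized stage derives its stream from
#'   it via [derive_seed()].
#' @param fixture_overrides passed to [make_fixture()].
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(fixture = c("eq33", "ou_beta010", "ou_beta015"),
                              offset_name = "none", offset_values = 0,
                              n = NULL, kappa = NULL, n_test = 500L,
                              reps = 50L, l = 2000L,
                              prior_moments = c("analytic", "simulated"),
                              alpha1 = 0.5, substeps = 10L, seed = 1L,
                              fixture_overrides = list()) {
  fixture <- match.arg(fixture)
  fx <- make_fixture(fixture, fixture_overrides)
  if (is.null(n)) n <- fx$n
  if (is.null(kappa)) kappa <- fx$kappa
  if (any(n <= fx$Np))
    stop("every training size must exceed Np = ", fx$Np,
         " for the data-driven QDA")
  stopifnot(n_test >= 1L, reps >= 1L, l > fx$Np)
  offset_name <- match.arg(offset_name, c("none", "dmu", "drho", "dbeta"))
  structure(list(fixture = fx, offset_name = offset_name,
                 offset_values = offset_values, n = as.integer(n),
                 kappa = kappa, n_test = as.integer(n_test),
                 reps = as.integer(reps), l = as.integer(l),
                 prior_moments = match.arg(prior_moments),
                 alpha1 = alpha1, substeps = as.integer(substeps),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the drift/dispersion misspecification experiment
#'
#' Executes, for every (offset, n, kappa) cell, `reps` independent
#' replicates of the protocol: simulate training paths per class from the
#' ground-truth SDEs; build a normal-inverse-Wishart prior from the
#' (possibly offset) a-priori SDE moments with `nu = kappa = Np + kappa`;
#' update it with the training paths and classify fresh test paths with
#' the OBC; train the data-driven QDA on the same paths; and score both
#' against the plug-in Bayes reference built from `l` ground-truth sample
#' paths.  Errors are averaged over replicates with Monte-Carlo standard
#' errors.
#'
#' @param config an [experiment_config()] with an `eq33`-compatible
#'   offset (`"none"`, `"dmu"` or `"drho"`).
#' @return An `error_table` data frame with one row per
#'   (classifier, n, kappa, offset) cell: columns `classifier`, `n`,
#'   `kappa` (the offset added to `Np`), `offset_name`, `offset_value`,
#'   `mean_error`, `mc_se`, `bayes_error`, `bayes_se`.
#' @seealso [run_ou_experiment()], [plot.error_table()]
#' @export
run_synthetic_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (!config$offset_name %in% c("none", "dmu", "drho"))
    stop("the synthetic experiment varies 'dmu' or 'drho'")
  run_protocol(config)
}

#' Run the trait-evolution (Ornstein-Uhlenbeck) experiment
#'
#' Same protocol as [run_synthetic_experiment()] with the OU
#' quantitative-trait fixtures as ground truth and the a-priori class-1
#' adaptation rate offset by `dbeta`.
#'
#' @param config an [experiment_config()] built on an OU fixture with
#'   `offset_name` `"none"` or `"dbeta"`.
#' @inherit run_synthetic_experiment return
#' @export
run_ou_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (!config$offset_name %in% c("none", "dbeta"))
    stop("the trait-evolution experiment varies 'dbeta'")
  if (config$fixture$name == "eq33")
    stop("use an OU fixture ('ou_beta010' or 'ou_beta015')")
  run_protocol(config)
}

run_protocol <- function(config) {
  fx <- config$fixture
  grid <- fx$grid
  Np <- fx$Np
  a1 <- config$alpha1
  rows <- list()
  for (oi in seq_along(config$offset_values)) {
    ov <- config$offset_values[oi]
    ap <- apriori_specs(fx, config$offset_name, ov)
    # Bayes reference: plug-in QDA from ground-truth moments.  Analytic
    # moments give the exact Bayes rule, which genuinely lower-bounds every
    # classifier; the simulated route (l paths) is only an estimate of it.
    bayes <- build_qda_from_sde(
      fx$spec0, fx$spec1, grid, alpha1 = a1,
      moment_source = config$prior_moments,
      l = config$l, seed = derive_seed(config$seed, "bayes", oi),
      substeps = fx$substeps)
    # a-priori SDE moments (shared across n and kappa within this offset)
    ap_list <- list(ap$spec0, ap$spec1)
    ap_mom <- lapply(seq_along(ap_list), function(w) {
      if (config$prior_moments == "analytic")
        stacked_moments(ap_list[[w]], grid)
      else
        sde_moment_estimate(ap_list[[w]], grid, l = config$l,
                            seed = derive_seed(config$seed, "prior", oi, w),
                            substeps = fx$substeps)
    })
    for (ni in seq_along(config$n)) {
      n <- config$n[ni]
      for (ki in seq_along(config$kappa)) {
        hyper <- Np + config$kappa[ki]
        pri0 <- niw(ap_mom[[1L]]$mean, (hyper - Np - 1) * ap_mom[[1L]]$cov,
                    nu = hyper, kappa = hyper)
        pri1 <- niw(ap_mom[[2L]]$mean, (hyper - Np - 1) * ap_mom[[2L]]$cov,
                    nu = hyper, kappa = hyper)
        err <- matrix(NA_real_, config$reps, 3L,
                      dimnames = list(NULL, c("obc", "qda", "bayes")))
        for (r in seq_len(config$reps)) {
          s <- derive_seed(config$seed, "cell", oi, ni, ki, r)
          tr0 <- simulate_paths(fx$spec0, grid, n, fx$substeps,
                                seed = derive_seed(s, "train", 0L), label = 0L)
          tr1 <- simulate_paths(fx$spec1, grid, n, fx$substeps,
                                seed = derive_seed(s, "train", 1L), label = 1L)
          te0 <- simulate_paths(fx$spec0, grid, config$n_test, fx$substeps,
                                seed = derive_seed(s, "test", 0L))
          te1 <- simulate_paths(fx$spec1, grid, config$n_test, fx$substeps,
                                seed = derive_seed(s, "test", 1L))
          obc <- build_obc(posterior_update(pri0, tr0),
                           posterior_update(pri1, tr1), alpha1 = a1)
          qda <- build_qda_from_data(tr0, tr1, alpha1 = a1)
          err[r, "obc"] <- true_error(obc, te0, te1, a1)
          err[r, "qda"] <- true_error(qda, te0, te1, a1)
          err[r, "bayes"] <- true_error(bayes, te0, te1, a1)
        }
        se <- apply(err, 2L, stats::sd) / sqrt(config$reps)
        mn <- colMeans(err)
        for (cl in c("obc", "qda")) {
          rows[[length(rows) + 1L]] <- data.frame(
            classifier = cl, n = n, kappa = config$kappa[ki],
            offset_name = config$offset_name, offset_value = ov,
            mean_error = mn[[cl]], mc_se = se[[cl]],
            bayes_error = mn[["bayes"]], bayes_se = se[["bayes"]])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("error_table", "data.frame")
  out
}

#' @export
print.error_table <- function(x, digits = 4, ...) {
  cfg <- attr(x, "config")
  if (!is.null(cfg))
    cat(sprintf(
      "Expected true error over %d replicates (%s fixture, %d test paths/class, root seed %d)\n",
      cfg$reps, cfg$fixture$name, cfg$n_test, cfg$seed))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Plot expected error against training size
#'
#' One panel per offset value: mean OBC and QDA errors as functions of the
#' per-class training size, one line per kappa, with the plug-in Bayes
#' error as a dashed reference.
#'
#' @param x an `error_table`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.error_table <- function(x, ...) {
  offs <- unique(x$offset_value)
  kappas <- unique(x$kappa)
  old <- graphics::par(mfrow = c(1, length(offs)))
  on.exit(graphics::par(old))
  for (ov in offs) {
    sub <- x[x$offset_value == ov, ]
    ns <- sort(unique(sub$n))
    cols <- cbind(
      sapply(kappas, function(k)
        sub$mean_error[sub$classifier == "obc" & sub$kappa == k][order(sub$n[sub$classifier == "obc" & sub$kappa == k])]),
      sapply(kappas, function(k)
        sub$mean_error[sub$classifier == "qda" & sub$kappa == k][order(sub$n[sub$classifier == "qda" & sub$kappa == k])]))
    graphics::matplot(ns, cols, type = "b", lty = 1,
                      pch = rep(c(1, 4), each = length(kappas)),
                      xlab = "training paths per class",
                      ylab = "expected true error",
                      main = sprintf("%s = %g", unique(sub$offset_name), ov),
                      ...)
    graphics::abline(h = mean(sub$bayes_error), lty = 2)
    graphics::legend("topright", bty = "n", cex = 0.8,
                     legend = c(paste0("OBC, kappa=Np+", kappas),
                                paste0("QDA, kappa=Np+", kappas), "Bayes"),
                     lty = c(rep(1, 2 * length(kappas)), 2),
                     pch = c(rep(c(1, 4), each = length(kappas)), NA))
  }
  invisible(x)
}
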