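# sdeclass

Optimal Bayesian classification of stochastic-process sample paths when
prior knowledge about the dynamics is available as **linear vector
stochastic differential equations (SDEs)**.

## The problem

Given trajectories observed at a common set of times
$t_1 < \dots < t_N$, which of two dynamical regimes produced a new one?
When each class is a $p$-dimensional Gaussian process, stacking the
observations turns this into Gaussian classification in $Np$ dimensions --
but with few training trajectories the sample covariances are singular or
wildly unstable exactly where biological data live (trait evolution,
regulatory dynamics, physiological signals).  Mechanistic knowledge is
often available, however, as a linear SDE per class:

$$dX_t = \bigl(A^y(t)\,X_t + a^y(t)\bigr)\,dt + B^y(t)\,dW_t,
  \qquad X_{t_0} = c^y .$$

Its solution is a Gaussian process whose stacked mean $m$ and block
covariance $\Psi$ follow in closed form from the fundamental matrix of the
drift.  `sdeclass` maps these moments into a normal-inverse-Wishart prior,

$$\breve m = m, \qquad \breve\Psi = (\kappa - Np - 1)\,\Psi ,$$

so the prior mean of $(\mu, \Sigma)$ reproduces the SDE moments exactly,
with $\nu, \kappa$ expressing how much the SDEs are trusted.  Conjugate
updating with training paths then yields the **optimal Bayesian classifier
(OBC)**: the rule that compares the posterior-averaged (effective)
class-conditional densities, which are multivariate Student-$t$, weighted
by the known class probabilities.  The package also provides the two
baselines the OBC is judged against -- data-driven quadratic discriminant
analysis (QDA) and the plug-in Bayes rule built from the true moments --
plus an Euler–Maruyama simulator and the full misspecification study
protocol, including an Ornstein–Uhlenbeck model of quantitative-trait
evolution.

## Worked example

Two species evolve a quantitative trait towards different optima
($\theta^0 = 80$ vs $\theta^1 = 85$) under the Ornstein–Uhlenbeck model
$dX = -\beta(X - \theta)\,dt + \sigma\,dW$ with adaptation rate
$\beta = 0.1$, observed over 30 time steps.  We classify trajectories with
100 training paths per class and a correct, strongly trusted SDE prior
($\nu = \kappa = Np + 500$):

```r
library(sdeclass)

sp0 <- ou_spec(beta = 0.1, theta = 80, sigma = 1, xa = 1)
sp1 <- ou_spec(beta = 0.1, theta = 85, sigma = 1, xa = 1)
g   <- obs_grid(1:30)

pr0 <- prior_from_sde(sp0, g, nu = 530, kappa = 530)
pr1 <- prior_from_sde(sp1, g, nu = 530, kappa = 530)
tr0 <- simulate_paths(sp0, g, n = 100, seed = 1, label = 0)
tr1 <- simulate_paths(sp1, g, n = 100, seed = 2, label = 1)

obc <- build_obc(posterior_update(pr0, tr0), posterior_update(pr1, tr1))
obc
#> Gaussian-process classifier: optimal Bayesian classifier (OBC)
#>   stacked dimension Np = 30, alpha1 = 0.5
#>   effective densities: multivariate t, dof k0 = 601, k1 = 601

qda   <- build_qda_from_data(tr0, tr1)     # no prior knowledge
bayes <- build_qda_from_sde(sp0, sp1, g)   # exact Bayes rule

te0 <- simulate_paths(sp0, g, 1000, seed = 3)
te1 <- simulate_paths(sp1, g, 1000, seed = 4)
true_error(obc,   te0, te1)   # 0.089
true_error(qda,   te0, te1)   # 0.206
true_error(bayes, te0, te1)   # 0.083
```

The OBC (8.9% error) sits essentially on the Bayes floor (8.3%) while QDA,
estimating a 30×30 covariance from 100 paths, pays more than double
(20.6%).  The misspecification studies
(`run_synthetic_experiment()`, `run_ou_experiment()`) quantify how this
advantage erodes -- and eventually reverses -- as the a-priori SDEs drift
away from the truth while confidence $\kappa$ stays high.

A thin command-line interface over the same functions (subcommands
`fixtures`, `simulate`, `classify`, `experiment`) is installed at
`inst/scripts/sdeclass`.

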