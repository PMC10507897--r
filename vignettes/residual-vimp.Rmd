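---
title: "Residual permutation importance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual permutation importance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resvimp)
```

## The problem

Permutation variable importance (VIMP) is the standard tool for attaching
meaning to random forest predictions: the importance of a predictor $X_i$ is
the increase in out-of-bag (OOB) prediction error caused by randomly
permuting its values,

$$\mathrm{VIMP}(X_i) \;=\; E\left[L\!\big(Y, f(\pi_i(X))\big)\right] -
  E\left[L\!\big(Y, f(X)\big)\right],$$

with $L$ the squared error in regression forests and the 0-1 loss in
classification forests, and $\pi_i$ a random permutation of the $i$-th
coordinate. VIMP measures *marginal* influence. When the predictor of
interest — call it $Z$ — is correlated with other predictors, its VIMP can be
high even though most of its information is also carried by those other
variables. A canonical example from transplantation research: a donor-organ
quality score is correlated with recipient characteristics (age,
comorbidities) because of how organs are allocated, so a large VIMP for the
score may be partly "borrowed" from them.

## The method

The package decomposes $Z$ into a part explained by the remaining predictors
$X_{-p}$ and a residual part. A model class $G$ is chosen and the best fit
$g \in G$ of $Z$ on $X_{-p}$ under squared error is computed, giving

$$Z = g(X_{-p}) + \varepsilon_Z.$$

Two forests are then compared:

* **model A** — the original forest on $(X_{-p}, Z)$; its VIMP for $Z$ is
  $\mathrm{VIMP}_A(Z)$, the marginal importance;
* **model B** — the adjusted forest on $(X_{-p}, \varepsilon_Z)$; its VIMP
  for the residual column is $\mathrm{VIMP}_B(\varepsilon_Z)$, the importance
  of the part of $Z$ the other predictors cannot explain.

A drop from $\mathrm{VIMP}_A(Z)$ to $\mathrm{VIMP}_B(\varepsilon_Z)$ means
part of $Z$'s importance originates in correlated predictors; a
$\mathrm{VIMP}_B(\varepsilon_Z)$ above zero means $Z$ contributes information
of its own. Two one-sided hypotheses formalize this:

* $H_0^{(1)}\!: \mathrm{VIMP}_A(Z) = \mathrm{VIMP}_B(\varepsilon_Z)$ against
  a larger marginal importance;
* $H_0^{(2)}\!: \mathrm{VIMP}_B(\varepsilon_Z) = 0$ against a positive
  residual importance.

### The resampling test

The sampling distribution of $\mathrm{VIMP}_B(\varepsilon_Z)$ is estimated by
subsampling: $m$ subsamples of $\lfloor 0.632\,n + 0.5\rceil$ rows are drawn
*without replacement*; in each, $g$ is refit from scratch, the residuals are
recomputed, the adjusted forest is retrained, and the residual VIMP recorded.
Subsampling (rather than a second bootstrap) avoids duplicated rows, which
would let the same observation be both in-bag and out-of-bag inside the
forest; the 0.632 fraction matches each row's inclusion probability under a
size-$n$ bootstrap.

Finite-sample VIMPs are attenuated: estimates from samples of size $0.632\,n$
are systematically smaller than full-sample estimates. The empirical density
is therefore shifted so that its mean equals the full-sample
$\mathrm{VIMP}_B(\varepsilon_Z)$ before any decision is taken. On the shifted
density, $H_0^{(1)}$ is rejected when $\mathrm{VIMP}_A(Z)$ exceeds the
empirical $(1-\alpha)$-quantile, and $H_0^{(2)}$ when the $\alpha$-quantile
exceeds zero. Reported p-values use the add-one resampling correction
$(1 + \#\{\cdot\})/(m+1)$, so the smallest attainable p-value is $1/(m+1)$.

```{r example}
d <- generate_design_a(scenario_spec(n = 300, c = 0.6, target_C = 0.6,
                                     target_spC = 0.2, seed = 1))
fit <- rvimp(d, z = "Z", m = 100, forest = forest_spec(num_trees = 100),
             seed = 1)
fit
```

## Tunable parameters

* `m` (default 100): number of subsamples. The density's tail quantiles
  govern both decisions, so `m` below 100 triggers a warning and below 20 an
  error. Runtime is linear in `m`.
* `subsample_fraction` (default 0.632): see above; changing it breaks the
  correspondence with the bootstrap inclusion probability and should be rare.
* `alpha` (default 0.05): level of each one-sided test.
* `forest_spec()`: 500 trees by default, `mtry = floor(sqrt(p))`
  (classification) or `max(floor(p/3), 1)` (regression), minimum node size
  1/5, bootstrap of size `n` with replacement — the conventions of the
  mainstream forest implementations. The same spec is used for the
  full-sample and every subsample forest.
* `g`: `"ols"` for low-dimensional problems (and for all packaged simulation
  studies), `"ridge"` when overfitting needs an explicit penalty, `"rf"` for
  non-additive dependence. An overfit $g$ makes residuals — and hence the
  residual importance — artificially small; the forest variant therefore
  derives its training residuals from OOB predictions. Cross-validated
  residual extraction is deliberately not implemented.
* `n_perm` (default 1): permutations per tree inside each VIMP; one
  permutation per tree is the standard convention, larger values reduce
  Monte-Carlo variance at proportional cost.

## Numerical conventions

These choices affect decisions at the margin and are fixed, not configurable:

* Quantiles interpolate linearly between adjacent order statistics (type 7).
* Rejection uses strict inequalities (`vimp_a > q_upper`, `q_lower > 0`).
* Subsample size rounds half up.
* Negative VIMPs are kept as-is; truncating at zero would bias the
  resampling density.
* Trees without OOB rows (possible in tiny samples) are dropped from all
  per-tree averages, with a warning.
* Per-tree class predictions and split tie-breaks are those of the `ranger`
  backend; they are deterministic under the recorded seed.
* Residual vectors whose largest entry is below `1e-10` (relative to the
  scale of `z`) are snapped to exactly zero: they represent an exactly
  explained `z`, and forests must not split on rounding noise. A constant
  column has permutation importance exactly 0.
* Every stochastic step (bootstrap, permutations, subsample draws, `g`
  refits) consumes a child seed spawned deterministically from the master
  seed, so results are independent of evaluation order and of whether
  companion importances are computed.

## The simulation designs

The built-in generator covers two designs used to study the test's level and
power without any external data. Features $X_1,\dots,X_5$ are standard normal
with $\mathrm{corr}(X_1, X_2) = c$ and all other pairwise correlations zero;
$Z = 0.5 X_1 + 0.5 X_2 + \varepsilon_2$, $\varepsilon_2 \sim N(0,
\sigma_2^2)$.

* **Design A** (regression): $Y = b_1 X_1 + \dots + b_5 X_5 + b_6 Z +
  \varepsilon_1$, $\varepsilon_1 \sim N(0, \sigma_1^2)$, with default
  coefficients $b = (0.5, 0.5, 1, 0, 0, 1)$.
* **Design B** (classification): $Y \sim \mathrm{Bernoulli}(p)$ with
  $p = \mathrm{logit}^{-1}(b_1 X_1 + \dots + b_6 Z + \varepsilon_1)$,
  $b = (1, 1, 1, 0, 0, 0)$, $c = 0.3$, $\sigma_1^2 = 4.04$,
  $\sigma_2^2 = 0.26$. The noise sits inside the inverse logit, so
  $E(Y) = 1/2$.

In design A the population correlation $C(Y, Z)$ and semipartial correlation
$spC(Y, Z \mid X_1..X_5) = C(Y, \varepsilon_2)$ are available in closed form
(`theoretical_moments()`), and `solve_sigmas()` inverts them: given targets
$(C, spC)$ it reduces the two-equation system to a one-dimensional root find
in $\mathrm{Var}(Y)$ and recovers $(\sigma_1^2, \sigma_2^2)$ to $10^{-8}$,
with infeasible targets rejected rather than clipped. The solved variances
are validated against sample correlations of $10^6$-row simulations in the
test suite. In these designs $H_0^{(1)}$ is true when $C = spC$ and
$H_0^{(2)}$ is true when $spC = 0$ (equivalently $b_6 = 0$).

Two study conventions follow the design's usual calibration: $c$ is set equal
to the target $C(Y, Z)$, and the "no semipartial correlation" configuration
($b = (1, 1, 1, 0, 0, 0)$) reuses the design B noise pair
$\sigma_1^2 = 4.04$, $\sigma_2^2 = 0.26$, since with $b_6 = 0$ the variances
are not identified by the (then degenerate) targets.

`run_rejection_study()` wraps the full loop — generate, test, tabulate — with
per-replication seeds derived by hashing (master, scenario, replication), so
studies are reproducible, order-independent and resumable from a checkpoint
file.

### What the generator does and does not emulate

The designs are low-dimensional, Gaussian, additive, and have a single
correlated block ($X_1, X_2, Z$). They exercise exactly the mechanism the
test targets — importance borrowed through correlation — under controlled
truth values of both hypotheses. They do not emulate high-dimensional
feature sets, non-linear dependence of $Z$ on the other predictors,
heavy-tailed or discrete features, or censored survival outcomes. Passing
level/power checks on these designs therefore demonstrates calibration of
the machinery under the stated conditions, not performance guarantees on
arbitrary real data.

## Problem sizes of the packaged checks

Simulation-backed checks in this package are run at what a desk machine
handles comfortably, as the package's own reduced scale: rejection-rate
studies use $n = 500$, $m = 100$, 100-tree forests and 200 replications in
the acceptance script, and 25–40 replications in the test suite. Where a
check compares an empirical rate against a reference value established at
1000 replications, the comparison band is widened a priori by twice the
binomial standard error of the reduced replication count — a deterministic
function of the reference rate and the replication number, never of the
observed outcome. Monotonicity checks allow an apparent decrease of up to
twice the pooled Monte-Carlo standard error.

## Known limitations

* The test concerns one pre-selected feature of interest. Testing several
  features, or using the results for variable selection, raises
  multiplicity and interpretation issues the package deliberately does not
  address.
* Neither causal pathways nor their direction can be inferred; a rejected
  $H_0^{(1)}$ says importance is shared, not which variable generates it.
* The decomposition inherits the quality of $g$: a misspecified $g$ leaves
  shared information in the residuals and understates the correlation
  effect, while an overfit $g$ overstates it.
* The subsample density estimates the variability of the *residual*
  importance; the H0(1) decision implicitly assumes the marginal importance
  of `z` is no more variable. For correlated features under 0-1 loss
  (classification), the marginal VIMP can fluctuate across datasets more
  than the residual-importance density suggests, which makes the H0(1)
  comparison aggressive for such features — rejection rates for them should
  be read together with the importance magnitudes, not in isolation.
* Absolute VIMP magnitudes depend on forest hyperparameters and the backend;
  rejection rates are much more stable than raw importances, and only rates
  are treated as reproducible quantities.
* Survival forests (C-index or weighted losses) are out of scope.
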