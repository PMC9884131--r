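---
title: "Controlling over- and under-prediction with a one-sided penalty"
author: "obreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling over- and under-prediction with a one-sided penalty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obreg)
```

## The problem

A regression model trained to minimize a symmetric loss treats a
prediction 10 units above the target exactly like one 10 units below it.
In many applications the two errors have very different costs: a public
health agency that under-predicts daily case counts during an epidemic
surge under-provisions hospital beds, and a maintenance planner that
over-predicts a machine's remaining useful life (RUL) schedules repairs
too late. Classical regularization (ridge, lasso) controls the magnitude
of the coefficients, not the *direction* of the errors; tuning it cannot
systematically reduce the number of over- or under-predicted instances.

`obreg` implements a simple convex remedy: a one-sided penalty on the
signed residuals that is added to any convex regression objective.

## The penalty

Write the model $h(x) = W^\top \Phi(x) + b$ and the signed residuals
$e_i = h(X_i) - y_i$, so that $e_i > 0$ is an over-prediction. The
penalty is

$$
\Psi(e) \;=\; \sum_i \bigl(\mathrm{sgn}(e_i) + 1\bigr)\,\lvert e_i\rvert^p
\qquad\text{(over-prediction control)}
$$

or, with $-\mathrm{sgn}(e_i)+1$ in place of the first factor,
under-prediction control. The sign factor is $2$ on the penalized side,
$0$ on the other, and $0$ at an exact hit ($\mathrm{sgn}(0) = 0$; the
summand vanishes at $e=0$ for every $p \ge 1$, so that choice is inert).
The penalty enters the objective as

$$
\hat L(y, h(X)) \;+\; \frac{\beta}{2}\,\Psi(h(X) - y),
$$

with $\beta \ge 0$ the strength of the side control. Because each
summand is a composition of the convex map $e \mapsto 2\lvert e\rvert^p$
restricted to a half-line with value $0$ elsewhere, $\Psi$ is convex for
$p \ge 1$, and adding $(\beta/2)\Psi$ to a strictly convex base loss
keeps the objective strictly convex — the fitted optimum is global. The
package verifies this numerically rather than symbolically: the test
suite checks the midpoint inequality
$f\!\left(\frac{a+b}{2}\right) \le \frac{f(a)+f(b)}{2}$ on thousands of
random parameter segments of the full regularized cost (tolerance
$10^{-9}$ absolute, which absorbs floating-point noise on well-scaled
costs).

Throughout the package $p = 2$ is the default; $\lvert e \rvert^p$ is
used rather than $e^p$ so the penalty stays well defined for odd $p$.
For $p = 2$ the penalty is continuously differentiable (the one-sided
quadratic meets zero with matching slope), which is what makes the
solvers below straightforward.

### Normalization

$\Psi$ as written is a raw sum while the usual empirical risk
$\hat L = \frac1n \sum_i \ell_i$ carries $1/n$. `bias_penalty()`
therefore defaults to `normalization = "mean"` (divide $\Psi$ by $n$) so
that a given $\beta$ has comparable strength across sample sizes and
$\beta$-grids transfer between experiments; `normalization = "sum"`
matches the raw-sum formulation literally. The choice matters when the
base term is itself a raw sum: the $\epsilon$-insensitive SVR objective
$\frac12\lVert\omega\rVert^2 + C\sum_i \max(0,\lvert e_i\rvert -
\epsilon)$ scales with $n$, so pairing it with a mean-normalized penalty
makes $\beta$'s effect shrink as $1/n$. The SVR examples in this package
therefore use `normalization = "sum"`, and the RUL demonstration runs at
raw scales (RUL in cycles, $C = 10$, $\epsilon = 5$, $\beta = 1$), where
the penalty is commensurate with the hinge term.

## Estimators

### Penalized linear regression: `oblm()`

`oblm()` minimizes

$$
\frac1n \sum_i (h(X_i) - y_i)^2 + \frac{\beta}{2}\Psi
 + \lambda_2 \lVert W\rVert_2^2 + \lambda_1 \lVert W\rVert_1 ,
$$

with $\Phi$ the identity and the intercept never penalized. The solver
starts from the deterministic point $W = 0$, $b = \bar y$, runs BFGS
with analytic gradients, and then — for the smooth case $p = 2$,
$\lambda_1 = 0$ — polishes with exact active-set steps: with the
penalized side fixed, the objective is a weighted ridge problem with
per-observation weights $\frac1n + \beta\,m\,\mathbf 1[e_i \text{ on the
penalized side}]$ ($m = 1/n$ under mean normalization, $1$ under sum),
solved in closed form; the active set is then refreshed and the step
accepted only if the exact objective decreases (backtracking line
search). Because the objective is piecewise quadratic and $C^1$, the
fixed point of this iteration is the global minimum, and at $\beta = 0$
a single step reproduces ordinary least squares to machine precision.
The recorded `cost_path` is non-increasing by construction, and
`converged` reports whether the final (sub)gradient norm is below `tol`
(default $10^{-8}$). With $\lambda_1 > 0$ the $\ell_1$ term is handled
by its subgradient inside BFGS, and convergence is assessed on the
minimal-norm subgradient; this is adequate for the mild lasso weights
the sweep driver uses, and an exact proximal solver was deliberately
left out of scope.

### Penalized support vector regression: `obsvr()`

`obsvr()` minimizes the unconstrained primal equivalent of the classical
slack formulation,

$$
\frac12\lVert\omega\rVert^2
 + C \sum_i \max(0, \lvert h(X_i) - y_i\rvert - \epsilon)
 + \frac{\beta}{2}\Psi ,
$$

because the added $\Psi$ term breaks the standard dual derivation; the
slack variables $\xi_i^\pm$ of the constrained form correspond exactly
to the two plus-functions $\max(0, \pm e_i - \epsilon)$. Residuals
strictly inside the $\epsilon$-tube contribute nothing. For the RBF
kernel the model is expressed on the training Gram matrix
($h(x) = \sum_j \alpha_j K(x_j, x) + b$,
$\lVert\omega\rVert^2 = \alpha^\top K \alpha$). The hinge is minimized
by graduated smoothing: each plus-function is replaced by its quadratic
smoothing of width $\mu$ (exact outside $(0, \mu)$), BFGS is run, and
$\mu$ is decreased over three stages from $10^{-1}$ to $10^{-6}$ times
the response scale; the reported `final_cost` is always the exact
non-smoothed objective, and a stage is accepted only if it does not
increase it. The procedure is deterministic, so identical inputs give
bit-identical fits. At $\beta = 0$ the resulting primal objective agrees
with a reference dual solver (`e1071::svm`) to well below $10^{-3}$ in
the test suite — the reference is used only as a cross-check, never as
the implementation.

### Plug-in loss for external models

The case for the penalty is architecture-independent: any model trained
by gradient descent on a differentiable loss can use it.
`make_loss_plugin()` packages $\mathrm{MSE} + (\beta/2)\Psi$ and its
exact prediction-space gradient as a pair of functions, validated
against central finite differences. Recurrent architectures themselves
(the natural fit for case-count forecasting) are out of scope here; the
windowed linear forecaster below plays that role at desk scale.

## Asymmetric evaluation

`evaluate_predictions()` reports, besides MSE and $r^2$, the mean
squared positive error (MSPE, over residuals $e > 0$), the mean squared
negative error (MSNE, over $e < 0$), and the side counts and rates. One
sign convention is fixed everywhere: **positive error means
over-prediction** ($e = \hat y - y > 0$), matching the
$\mathrm{sgn}(h(X_i) - y_i)$ inside the penalty. Informal usage in the
field sometimes flips which side "positive error" names; fixing the
convention at the definition of $e$ and documenting it avoids that
ambiguity. Empty sides report $0$ with a count of $0$ rather than `NaN`
so sweep tables stay finite, and the exact partition
$n\,\mathrm{MSE} = n_{over}\,\mathrm{MSPE} + n_{under}\,\mathrm{MSNE}$
is asserted in tests. A zero-variance target makes $r^2$ undefined; the
report flags it (`r2_defined = FALSE`) instead of erroring.

`bias_variance_estimate()` implements the replicated-refit protocol:
fit the same procedure on many independently generated datasets, then at
each point of a fixed test grid compute the across-replicate variance of
the predictions and the squared gap between their mean and the true
noiseless response. The grid is 200 points spanning the generator's
feature range. Squared bias is reported (with per-replicate and
per-point detail retained, so a signed-bias view can be derived).
Replicate seeds are drawn deterministically from the master seed, so the
result is reproducible and independent of replicate ordering.

## Synthetic data: what it emulates, and what it does not

The three generators define the package's study conditions; none of
them claims realism beyond what the loss-behaviour questions need.

* `gen_linear(n, d, ...)` — features i.i.d. uniform on $[0,1]^d$,
  Gaussian noise. Defaults (used by the sweep driver): $n = 1000$,
  univariate slope $2$ (4-feature variant $1.5, -2, 1, 0.5$), intercept
  $1$, `noise_sd = 0.5`. The noise level gives a baseline training
  $r^2 \approx 0.57$ — a signal-to-noise regime where both sides of the
  residual distribution are well populated, so side-control effects are
  visible without being trivial.
* `gen_surge_series()` — a 534-day series (a realistic horizon for an
   18-month epidemic record) with baseline 50 counts/day, two Gaussian
  surges (day 150, height 400, width 20; day 380, height 900, width 25),
  observation noise SD 30, floored at zero. Gaussian bumps, not a
  mechanistic SEIR model: the object under test is the loss term's
  behaviour on surge-shaped curves, not epidemiology. Real case curves
  have reporting artifacts (weekday effects, dumps, autocorrelated
  noise) that this generator deliberately omits, so passing tests show
  the penalty controls under-prediction on surge-shaped signals — not
  that any particular real-world forecast would improve by the same
  amount.
* `gen_degradation()` — run-to-failure units with lifetimes uniform on
  $[128, 362]$ cycles (matching the RUL span typical of turbofan
  degradation benchmarks), RUL target $\text{lifetime} - t$ with no
  capping plateau (capping is a common alternative convention; it is
  intentionally off by default). Sensors read the health state linearly
  in RUL with per-unit slope heterogeneity (default $\pm 20\%$) plus
  noise; with both set to zero the RUL is exactly linearly decodable,
  which the tests exploit as a ground-truth case. Sensors are linear in
  remaining life rather than in the cycle index because a cycle count
  alone cannot identify $\text{lifetime} - t$ across units with
  different lifetimes.

All generators are pure functions of their arguments including the
seed, restore the global RNG state on exit, and carry a `truth` record
sufficient to regenerate the noiseless response exactly.

## Forecasting demonstration

`make_windows()` + `fit_forecaster()` + `rolling_evaluate()` form the
desk-scale analog of penalizing a sequence model's training loss: a
linear autoregression on a 14-day lag window, horizon 1, fitted on the
first 70% of windows and evaluated one-step-ahead on the rest without
refitting (deterministic, fast, and sufficient to expose surge
under-prediction; none of window, split or horizon is canonical, and
all are arguments). With `direction = "under"` and $\beta = 1$ on the
packaged two-surge series, the held-out under-predicted-day count drops
from 74 of 156 days to 61, with the squared error mass shifting from the
negative to the positive side — the qualitative signature of the method.
The packaged CSV (`inst/extdata/surge_synthetic.csv`) is synthetic,
generated by `gen_surge_series(seed = 42)`.

## The beta sweep

`run_beta_sweep()` reproduces the standard summary experiment: for each
$\beta$ on a grid (default $\{0, 0.01, 0.1, 1, 10\}$, a decade grid
bracketing the weights at which side-control effects turn on for
mean-normalized penalties at these scales), fit the model family on
replicate datasets and tabulate variance, bias$^2$, mean $r^2$, MSPE,
MSNE and side rates. Replicate dataset seeds depend only on the master
seed and the replicate index — not on the grid position — so the grid
can be extended without disturbing earlier rows and the comparison
across $\beta$ is paired. With the defaults (100 replicates,
$n = 1000$, univariate) the table shows the expected pattern: variance
nearly flat, bias$^2$ rising rapidly with $\beta$, mean $r^2$ falling,
MSPE falling and MSNE rising for over-side control. At $\beta = 0.01$
the penalty's systematic shift is of the same order as the Monte-Carlo
error of the 100-replicate bias estimate, so the bias$^2$ column can
tie (or negligibly dip) at that point for some seeds; the trend is
strict from $\beta = 0.1$ on.

Outputs are written as CSV with numbers fixed at 10 significant digits,
making repeated runs byte-identical. The YAML config mirrors the
`sweep_config()` arguments (`read_sweep_config()` keeps short keys like
`n` from being parsed as YAML booleans). Plots are left to the user —
the canonical artifact is the table.

## Numerical choices and edge cases

* Gradient tolerance $10^{-8}$ (linear solver), maximum 10000
  iterations; non-convergence is reported in the fit object, not raised.
* Subgradient at $e = 0$ chosen as $0$: a valid element of the
  subdifferential that leaves the unpenalized side exactly untouched.
* SVR smoothing widths scale with $\mathrm{sd}(y)$, so the solver is
  insensitive to the response's units.
* Degenerate inputs: empty data, dimension mismatches and non-finite
  values raise immediately with a specific message; a zero-variance
  target degrades $r^2$ to a flagged `NA`.
* Ties on the penalized side: counts may be flat across adjacent
  $\beta$ values (the penalty's effect can be absorbed by the intercept
  before any instance changes side); monotonicity claims in the tests
  allow ties.

## Limitations

* The fitted penalty controls the *training-set* side counts directly;
  held-out improvements (as in the forecasting demo) are an empirical
  consequence, not a guarantee.
* $\beta$ is not selected automatically; the sweep driver is the
  intended tool for choosing it against a user's asymmetric cost.
* The SVR solver targets small-to-moderate $n$ (the RBF path optimizes
  $n + 1$ parameters on a dense Gram matrix); it is a reference
  implementation of the penalized primal, not a large-scale SMO.
* Real epidemic and reliability datasets — with their preprocessing
  pipelines and deep sequence models — are intentionally outside the
  package; the synthetic generators bound what the test suite can
  claim.
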