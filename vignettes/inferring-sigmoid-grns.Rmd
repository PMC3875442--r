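---
title: "Inferring gene regulatory networks with the Vohradsky sigmoid ODE model"
author: "sigmoidGRN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene regulatory networks with the Vohradsky sigmoid ODE model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmoidGRN)
```

## The model

`sigmoidGRN` infers gene regulatory networks from time-series expression
data under the Vohradsky model, a recurrent-neural-network-like ODE
system: for each of $n$ genes,

$$\frac{dx_i}{dt} \;=\; k_{1,i}\,\sigma\!\Big(\sum_{j=1}^n w_{ij}\,x_j + b_i\Big)
\;-\; k_{2,i}\,x_i, \qquad \sigma(u) = \frac{1}{1+e^{-u}},$$

where $x_i \ge 0$ is the expression level of gene $i$, $k_{1,i} > 0$ is
its maximal synthesis rate, $k_{2,i} > 0$ its first-order degradation
rate constant, $b_i$ a bias, and $w_{ij}$ the signed strength with which
gene $j$ regulates gene $i$ ($w_{ij} = 0$: no regulation).  The model has
$n(n+3)$ parameters — comparable to a linear model — which makes it
attractive when time-course data are scarce.

Estimating all $n(n+3)$ parameters at once is a high-dimensional
non-convex problem.  The package instead solves $n$ independent
subproblems, one per gene, each requiring only the measured expression
matrix and an estimate of each gene's time derivative at every sample.

## Per-gene estimation: a 2-D search wrapping a linear program

Given derivative estimates $x'_{i,t}$, gene $i$'s model equation at each
sample $t$ can be rearranged, for a *candidate* pair $(k_1, k_2)$, into

$$y_t \;=\; \frac{x'_{i,t} + k_2\, x_{i,t}}{k_1}
\;\overset{!}{=}\; \sigma\Big(\sum_j w_{ij} x_{j,t} + b_i\Big),$$

and wherever $y_t \in (0, 1)$ the logit transform linearizes it:

$$z_t \;=\; \ln\frac{y_t}{1-y_t} \;=\; \sum_j w_{ij}\,x_{j,t} + b_i .$$

Because genetic networks are sparse, the weights are estimated by the
linear program

$$\min_{w, b, \xi}\; \sum_j |w_j| \;+\; \theta \sum_t c_t\, \xi_t
\quad\text{s.t.}\quad |z_t - (w \cdot x_t + b)| \le \xi_t,\; \xi_t \ge 0,$$

whose optimum is found by a Mehrotra predictor–corrector interior-point
method written for this package (with an exact revised-simplex fallback;
see *Numerical choices*).  The outer estimate of $(k_1, k_2)$ minimizes
the original-scale least-squares objective

$$f(k_1, k_2) \;=\; \sum_{t=1}^{M}
\Big[x'_{i,t} - k_1\,\sigma(\hat w \cdot x_t + \hat b) + k_2\,x_{i,t}\Big]^2,$$

evaluated over **all** $M$ samples — including those excluded from the
LP — so that a candidate $(k_1,k_2)$ cannot look good merely by
invalidating rows.  Both rates are searched in $\log_{10}$ space (they
are positive and span orders of magnitude).

### Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `theta` | L1-vs-residual trade-off in the LP | 2000 | larger = denser fits; sweeping it traces a precision–recall curve |
| `eps` | validity band: rows with $y_t \notin [\epsilon, 1-\epsilon]$ are excluded | $10^{-5}$ | the logit amplifies noise by $1/(y(1-y))$ near the boundary |
| `bounds` | $\log_{10}$ search box for $k_1, k_2$ | $[-2, 2]$ | rates in $[0.01, 100]$ per unit time |
| `successThreshold` | objective below which a subproblem counts as solved | $10^{-6}$ | suited to noise-free data; noisy fits plateau near $M \times$ the derivative noise variance |
| `weightFun` | per-equation LP weights $c_t$ | $y_t(1-y_t)/\max_t y_t(1-y_t)$ | pluggable; see below |

The per-equation weights $c_t$ down-weight equations whose $y_t$ sits
near 0 or 1: an additive error $\delta$ in $y$ becomes an error
$\approx \delta / (y(1-y))$ in $z$, so weighting by $y(1-y)$ (scaled to
maximum 1) counteracts exactly that amplification.  This particular
normalization is this package's choice; it is exposed as a function
argument so other weighting schemes can be substituted.

## The REX/JGG optimizer and its restart policy

The outer 2-D objective is multimodal — local search finds spurious
minima — so it is minimized with a real-coded evolutionary algorithm:
REX (real-coded ensemble crossover) inside the JGG (just generation gap)
scheme.  Each generation draws $n_p$ parents uniformly from the
population, produces children
$x = \bar{x} + \sum_j \xi_j (x_j - \bar{x})$ with
$\xi_j \sim N(0, s^2)$ around the parent centroid $\bar{x}$, and replaces
the parents with the best children.  Defaults for the 2-D search:
population 30, 3 parents, 10 children, step $s = 1/\sqrt{2}$, at most 200
generations per round, stall window 50.

A plain JGG population eventually collapses onto an incumbent, and on
this problem's narrow curved valleys that regularly happens short of the
optimum: in our measurements plain REX/JGG recovered all four genes of
the 4-gene reference system in 0 of 10 trials even with a 1500-generation
budget.  The minimizer therefore **restarts on stall**, alternating two
moves: a *zoom* round re-initializes the population in a box centred on
the best point whose width shrinks by a factor (default 0.2), and an
*exploration* round re-initializes over the full search box in case the
incumbent sits in a spurious basin; the incumbent is always injected
into the new population.  Up to 10 restarts are attempted by default,
and an optional `targetValue` stops the search early once the objective
is good enough.  With this policy the 4-gene experiment succeeds in 7-10
of 10 seeded trials with 0-3 of 40 single-gene failures (seed-dependent),
at the same per-generation settings.  A rank-weighted ("elitist-centre")
crossover variant was evaluated as an alternative accelerator and
performed worse at greater cost, so it is not included.

## Derivative estimation from noisy series

`smoothTimecourses()` fits a weighted local polynomial (tri-cube distance
weights) around every sample, independently per gene and per series; the
smoothed level is the fit value and the derivative is the fit's analytic
slope — never a finite difference of smoothed values, which would smooth
twice.  Defaults: degree 1, span 0.5 (the window is
`ceiling(span * length)` points, at least degree + 2).  On the synthetic
noisy benchmark (11 points per series, 10% noise) a local *quadratic*
with span ≈ 0.65 gave the smallest derivative error on held-out replica
instances, and the packaged noisy-benchmark comparison uses that
setting; with so few points per series the derivative signal-to-noise
ratio remains low (≈ 2), which bounds what any estimator can recover.

For real data in the style of the SOS DNA-repair time courses the
pipeline is: `normalizePerGeneMax()` (each gene scaled by its maximum
over all series), `dropInitialPoints()` (shared zero initial
concentrations cannot be reconciled by a deterministic ODE),
`smoothTimecourses()`, and `floorLowValues()` (expression must stay
nonnegative; default floor 0.001 on the normalized scale).

## The synthetic benchmark generator

`generateNetwork()` draws, per gene, an in-degree from a truncated power
law $P(k) \propto k^{-\gamma}$ on $\{1..5\}$, chooses that many
regulators uniformly, and assigns them weights with magnitudes uniform in
$[5, 20]$ and random signs; biases are uniform in $[-10, 10]$ and
synthesis rates uniform in $[0.1, 1]$.  The printed ranges of the
original benchmark description are not recoverable, so these defaults are
the package's own, chosen to produce strongly switching regulation on the
normalized $[0, 1]$ expression scale; $\gamma = 2$ by default.  By
default $k_{2,i} = k_{1,i}$, which matches the reference 4-gene system
and keeps steady states at or below 1; an independent-$k_2$ mode exists.
`generateTimecourses()` samples initial states uniformly in $[0, 1]$,
integrates the ODE at 11 equally spaced times on $[0, 10]$, and applies
multiplicative noise `clean * (1 + N(0, 0.1))` (the "10% Gaussian noise"
convention), floored at 0.

What the generator does *not* emulate: intrinsic (demographic) noise in
the dynamics themselves, non-Gaussian measurement error, missing samples,
and dynamics outside the Vohradsky family.  Passing the synthetic tests
therefore demonstrates correct estimation *within* the model family, not
performance on data whose generating process is different.

### Identifiability of generated instances

A random sparse network frequently contains *silent* genes — the sigmoid
input stays far below 0 over every reachable state, so the gene's
synthesis term never activates.  Such genes are structurally
unidentifiable from observational time courses: many parameter rows
reproduce the data exactly, and the reference 4-gene system used for
recovery experiments is, notably, a well-excited oscillator.  The
package's end-to-end recovery tests therefore screen generated instances
for identifiability *a priori*: at the true rates, every gene's valid
logit design $[X, 1]$ must have smallest singular value at least 0.3 (a
persistent-excitation condition).  Recovery to $10^{-3}$ is asserted only
on screened instances; on unscreened ones the objective still vanishes
but the minimum-L1 interpolant need not be the generator's parameter row.

## Numerical choices

* **Integration**: Dormand–Prince RK4(5) via `deSolve`, `rtol = 1e-8`,
  `atol = 1e-10`; results are integrator-robust (halving tolerances moves
  sampled values by $<10^{-6}$ relative).  Round-off below zero (under
  $10^{-8}$) is zapped; there is no other state clipping.
* **Interior point**: Mehrotra predictor–corrector on the split-variable
  equality form, normal equations $B D_B B^\top + D_r$ factorized by
  Cholesky with escalating regularization.  Double precision limits the
  attainable KKT quality to about $10^{-9}$; the solver keeps the best
  iterate seen and accepts it when its quality is below $10^{-7}$.
* **Simplex fallback**: the LP at a noise-free optimum is massively
  degenerate (every slack active), which interior-point methods handle
  poorly; a revised simplex with Bland's-rule anti-cycling takes over on
  failure, starting from the natural feasible basis $\xi = |z|$.  On
  systems with at most 40 rows the exact simplex is preferred over a
  merely "acceptable" interior-point iterate.
* **Penalty convention**: candidate rates that leave fewer than 2 valid
  rows, or an LP failure, score a large finite penalty ($10^{12}$), so
  the outer search never aborts.
* **Ties and degeneracies**: children violating the search box are
  resampled up to 10 times, then clipped; non-finite objective values are
  treated as $+\infty$; smoothing windows with fewer than degree + 1
  positively weighted points are widened (uniform weights as a last
  resort).

## Scaled-down experiments in the tests

The packaged tests reproduce the method's headline behaviour at desk
scale (sizes chosen as realistic-but-small study conditions):

* **Small-scale recovery**: 10 trials of the 4-gene reference system, 3
  noise-free series of 5 points each from random initial states, exact
  derivatives.  Expected: at least 7 trials with all four objectives
  below $10^{-6}$ and at most 3 of the 40 subproblems failed.
* **Noisy comparison**: one seeded 10-gene, 10-series, 11-point instance
  with 10% noise; both the sparse-LP method and the least-squares
  baseline (max in-degree 5, penalty weight 1) are fit on the same
  smoothed data, structures are swept over the threshold
  $\delta \in [0.01, 20]$, and the area under the sign-aware
  precision–recall curve must favour the sparse-LP method.  Absolute
  AUC values are low for both methods at this data volume — the
  derivative signal-to-noise ratio is the binding constraint.
* **LP correctness**: objective equality (to $10^{-8}$) with a
  brute-force basic-solution enumeration oracle on over one hundred random
  tiny instances.

## The least-squares baseline

`solveGeneLS()` minimizes the direct sum of squared residuals plus a
sorted-weight penalty $c \sum_{j > I} |w_{(j)}|$, where $w_{(1..n)}$ are
the weights ordered by descending magnitude and $I$ is the maximum
in-degree — only the $I$ largest-magnitude weights escape the penalty.
The same REX/JGG minimizer runs in $n + 3$ dimensions (weights and bias
in linear space within $[-30, 30]$, rates in log space), with
dimension-scaled defaults (population $15D$, $D+1$ parents, $8D$
children, stall window 150).

## Known limitations

* Parameter (as opposed to structure) estimates are unreliable under
  measurement noise; this mirrors the method's own character — in noise,
  evaluation should be structural (recall/precision/specificity).
* The equation-weight constants and several benchmark ranges of the
  original description are not recoverable from our copy; the package's
  defaults are documented reconstructions, and all are configurable.
* $\theta$ controls sparsity only weakly when derivative noise is large,
  because the weighted-residual term dominates the L1 term at any
  $\theta \gtrsim 20$; sweeping the structure threshold $\delta$ is the
  more effective way to trace a precision–recall curve at desk scale.
* Runtime is dominated by one LP solve per objective evaluation; genes
  are independent and can be processed in parallel by the caller.

## A complete noise-free run

```{r example, eval = FALSE}
fx <- smallScaleFixture(seed = 1)          # 4-gene reference system
fit <- inferNetwork(fx$data, fx$derivatives, seed = 1)
round(regWeights(fit$model), 3)            # recovered weight matrix
vapply(fit$results, `[[`, numeric(1), "objective")
extractStructure(fit$model, delta = 0.1)   # signed regulation structure
```
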