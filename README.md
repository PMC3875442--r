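# sigmoidGRN

Gene regulatory network inference from time-series expression data under
the Vohradsky sigmoid ODE model, for systems biologists who want an
ODE-based alternative to correlation- or regression-only network
inference when only a handful of short time courses are available.

## The method

Each gene's expression follows

    dx_i/dt = k1_i * sigmoid( sum_j w_ij x_j + b_i ) - k2_i * x_i

with synthesis rate `k1_i > 0`, degradation rate `k2_i > 0`, bias `b_i`,
and signed regulatory weights `w_ij` (zero = no regulation).  Instead of
fitting all `n(n+3)` parameters at once, the inference decomposes into
`n` independent per-gene subproblems.  For gene `i`, with derivative
estimates `x'_{i,t}` in hand:

1. for candidate rates `(k1, k2)`, the model equation linearizes through
   the logit: `logit((x'_{i,t} + k2 x_{i,t}) / k1) = sum_j w_ij x_{j,t} + b_i`;
2. the sparse weight row is the solution of the linear program
   `min sum_j |w_j| + theta * sum_t c_t xi_t` subject to
   `|z_t - (w . x_t + b)| <= xi_t` (interior-point solver, exact simplex
   fallback);
3. `(k1, k2)` themselves are found by a two-dimensional REX/JGG
   evolutionary search in log space, scoring each candidate by the
   original-scale sum of squared residuals over all samples.

The package also provides the forward simulator, a local-linear-
regression smoother producing analytic-slope derivative estimates, a
penalized least-squares comparison estimator, a synthetic benchmark
generator (power-law in-degrees, multiplicative Gaussian noise), and
structure-recovery metrics (recall / precision / specificity,
precision-recall curves).

## Worked example

Noise-free recovery of the 4-gene reference network:

```r
library(sigmoidGRN)
fx  <- smallScaleFixture(seed = 101)   # 3 series x 5 points, exact derivatives
fit <- inferNetwork(fx$data, fx$derivatives, seed = 42)
round(fit$results[[2]]$w, 3)
#> [1]  15.009 -10.013   0.005   0.001
round(c(k1 = fit$results[[2]]$k1, k2 = fit$results[[2]]$k2), 4)
#>     k1     k2
#> 0.1999 0.1998
signif(vapply(fit$results, `[[`, numeric(1), "objective"), 3)
#> [1] 7.86e-09 2.96e-09 2.77e-08 1.84e-06
```

Gene 2's true parameters are `w = (15, -10, 0, 0)`, `b = -5`,
`k1 = k2 = 0.2`: the estimator reproduces the weight row to ~0.01 and
the rates to ~2e-4 here.  A per-gene objective below `1e-6` marks the
subproblem as solved — genes 1-3 clear it in this run while gene 4 lands
just above; over 10 seeded trials, typically 7 trials solve all four
genes and at most 3 of the 40 subproblems fail.  The signed
structure follows with `extractStructure(fit$model, delta = 0.1)`, and
`confusionCounts()` / `networkMetrics()` score it against a reference
network.

For noisy data, estimate levels and derivatives first:

```r
m  <- generateNetwork(10, seed = 1)
tc <- generateTimecourses(m, nSeries = 10, noiseFraction = 0.1, seed = 2)
sm <- smoothTimecourses(tc$noisy, span = 0.65, degree = 2)
fit <- inferNetwork(sm$smoothed, sm$derivatives, seed = 3)
```

A thin command-line wrapper over these functions ships in
`inst/scripts/grn-tool.R` (subcommands `generate`, `simulate`, `smooth`,
`infer`, `infer-ls`, `evaluate`).

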