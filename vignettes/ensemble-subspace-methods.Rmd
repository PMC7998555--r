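---
title: "Random-subspace ensembles of penalized predictors: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-subspace ensembles of penalized predictors: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elsar)
```

## The prediction problem and the two devices

We observe $n$ pairs $(x_i, y_i)$ with $x_i \in \mathbb{R}^p$, $p \gg n$,
from the linear model $y = X\beta + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2 I)$, with $\beta$ sparse: $r$ of its $p$
entries are nonzero. The goal is out-of-sample prediction, and the
benchmark everything is measured against is the lasso with its penalty
chosen by 10-fold cross-validation (`CVLasso`).

`elsar` implements two devices that can beat that benchmark:

**Covariate subspaces.** An ensemble member sees all $n$ rows but only a
random subset of columns: the distinct covariates of a size-$p$
bootstrap draw (approach 1, expected size
$p\,(1-(1-1/p)^p) \approx 0.63p$), $n$ covariates without replacement
(approach 2), or $\lfloor n/2 \rfloor$ (approach 3). The ensemble
prediction is the plain mean of the $B$ member predictions. For members
with common variance $\sigma^2$ and pairwise correlation $\rho$, the
ensemble variance is
$$\mathrm{Var} = \rho\sigma^2 + \frac{(1-\rho)\sigma^2}{B},$$
so a large $B$ removes the second term and what remains is the
correlation floor $\rho\sigma^2$. Small subspaces decorrelate members;
that is the whole mechanism, and it is why approach-1 subspaces (which
overlap on ~63% of covariates but differ enough) tend to do best when
many covariates carry signal.

**Trimmed path averaging.** Every penalized fit is computed along a
fixed path of $L = 100$ penalty values, log-equally spaced from
$\lambda_{\max}$ — the smallest $\lambda$ at which all slopes are zero,
$\max_j |\langle x_j, y - \bar y\rangle| / (n\alpha)$ on standardized
columns — down to $\lambda_{\max} e^{-6}$. The `Tr` rule predicts, per
test point, with the mean of the 100 path predictions after discarding
the `floor(0.10 * L)` smallest and largest; the `CV` rule predicts at
the single path point minimizing 10-fold cross-validated error.
Trimming replaces a possibly unlucky CV choice with a robust summary of
the whole path: the sorted-prediction tails are exactly the overfitted
(tiny $\lambda$) and null (large $\lambda$) ends.

Trimming is applied to *per-test-point predictions*, not to
coefficients and not across ensemble members; the outer ensemble mean
is untrimmed. Where both devices are combined (`ETrLasso(1)` etc.),
each member runs its own path on its own subspace — $\lambda_{\max}$ is
recomputed per member because each member sees a different design.

## Penalty families

All families share the standardization convention (columns centered and
scaled to unit standard deviation with the $1/n$ denominator, matching
the internal convention of glmnet, which also solves the lasso and
elastic-net paths here) and return coefficients on the original scale.

* **Lasso / elastic net** — glmnet with the package's own
  $\lambda$ path; the lasso is the $\alpha = 1$ code path of the
  elastic net. Study values of $\alpha$: 0.25, 0.5, 0.75.
* **Adaptive lasso** — weights $w_j = 1/|\hat\beta_j^{\text{ridge}}|$
  from a preliminary ridge fit whose own penalty is chosen by 10-fold
  CV over a log-spaced grid; the weighted problem is solved as a plain
  lasso on rescaled columns $x_j / w_j$. The ridge solve uses the exact
  kernel-form identity (an $O(n^2 p)$ eigen decomposition), which is
  exact for $p \ge n$ and much faster than iterative solvers.
  $|\hat\beta_j|$ is floored at $10^{-8}$ (so $w_j \le 10^{8}$): a
  covariate at the floor is penalized so heavily it is effectively
  excluded. During cross-validation of the adaptive lasso the weights
  are computed once on the full training data and shared by all folds.
* **LARS** — the pure forward least-angle trajectory, which is indexed
  by steps, not by $\lambda$. The path-of-$L$ convention maps to $L$
  evenly spaced points along the trajectory from the null model to the
  final step at $\min(n-1, p)$ active variables, interpolating linearly
  in the step index; `CVLARS` cross-validates the point index.
* **SCAD** — a dedicated cyclic coordinate-descent solver
  (RcppArmadillo) using the three-piece univariate thresholding rule:
  soft-thresholding below $2\lambda$, a linear interpolation up to
  $a\lambda$, and no shrinkage beyond — the "nearly unbiased for large
  coefficients" property that motivates SCAD. Shape $a = 3.7$
  (the standard recommendation), path entry at the lasso
  $\lambda_{\max}$ (the zero vector is stationary there because the
  penalty derivative equals $\lambda$ near zero), warm starts,
  tolerance $10^{-7}$ on the maximum coefficient change,
  `max_iter = 10^4` with non-convergence flagged per path point. SCAD
  is nonconvex; the solver returns a stationary point.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `B` | 250 | ensemble size; results stabilise well before 250 (the $1/B$ variance term is already negligible), which is why reduced runs use 20–50 |
| `L` | 100 | path length; with the fixed $e^{-6}$ span this sets the log-spacing only |
| `trim_fraction` | 0.10 | per-tail trim of the $L$ path predictions |
| `K` | 10 | CV folds, everywhere CV appears |
| `a` | 3.7 | SCAD shape |
| `test_fraction` | 0.3 | held-out fraction: $n_0 = 0.3n$ test points per replicate (rounded), or 70/30 resplits of fixed data |

## The simulation models

`sim_preset()` provides the four random-design study configurations.
All draw, per replicate: coordinate means $\mu_i \sim N(5, 2)$;
a symmetric covariance with off-diagonals i.i.d. uniform and diagonal
$U(0.8, 1.2)$; a contiguous block of $r$ nonzero coefficients at a
uniformly drawn offset; rows $x_i \sim N(\mu, \Sigma)$; and Gaussian
noise.

| preset | off-diagonal | $\beta$ nonzeros | noise |
|---|---|---|---|
| `strong_corr` | $U(0.4, 0.6)$ | $U(-2, 2)$ | $N(0, 0.15)$ |
| `weak_corr` | $U(0, 0.2)$ | $U(-2, 2)$ | $N(0, 0.15)$ |
| `strong_beta` | $U(0, 0.2)$ | $U(2, 3)$ | $N(0, 0.15)$ |
| `weak_beta` | $U(0, 0.2)$ | $U(-0.2, 0.2)$ | $N(0, 0.15)$ |

Second arguments of the normal laws are read as **variances** (the
covariance notation of the design model is variance-based); a
`gaussian_second_arg = "sd"` switch exposes the other reading. The
difference only rescales $\mu$'s spread and the noise, and in the
strong-signal presets the signal-to-noise ratio is so high that
efficiency ratios barely move.

A drawn $\Sigma$ of this kind is routinely **indefinite** at large $p$
(the random fluctuation has spectral radius $\approx 2 \cdot 0.058
\sqrt p$, which swamps the smallest structural eigenvalue): it is
repaired by clipping eigenvalues at $10^{-6}$ and reassembling —
deterministic and cheap, at the cost of perturbing entries (for the
strongly correlated law at $p \ge 300$ the diagonal moves by up to
~0.2; for the weakly correlated law the perturbation stays well under
half the 0.2 diagonal span). The repaired eigen decomposition is reused
directly to sample rows, and the pre-repair minimum eigenvalue and
implied correlation range are recorded. Whether $\mu, \Sigma, \beta$
should be redrawn per replicate is a genuinely open choice; they are
redrawn (each replicate is an independent draw of the entire
mechanism), matching the independent-collections reading of the
protocol, and the per-replicate seed makes either convention
reproducible.

`make_synthetic_gene_design()` provides a deterministic
block-correlated Gaussian stand-in for a real expression matrix
(120×200, standardized columns, blocks of 20 probes with within-block
correlation drawn from $U(0.3, 0.8)$). It is synthetic: it emulates
only the column-correlation structure, not real expression values, and
results on it say nothing about any particular dataset. Real data enter
through plain CSV (`run_fixed_design()`, CLI `fit`/`run`).

## Evaluation protocols

Random design: per replicate, draw training ($n$) and test ($n_0 =
0.3n$) rows from one draw of the generating mechanism, fit **all**
methods on the same training data, score MSPE on the same test points,
and report per method the mean of per-replicate ratios
$\mathrm{MSPE}(\text{CVLasso}) / \mathrm{MSPE}(\text{method})$ — the
mean of ratios, not the ratio of means — with its Monte-Carlo standard
error and the win fraction. Fixed design: repeated seeded 70/30 row
splits of one dataset, optionally regenerating the response on the
fixed design each resplit (contiguous $U(-2,2)$ coefficient block,
noise variance 0.4 — sized so that noise is comparable to the ~0.28
average predictor spread on standardized designs). A method failure
drops the whole replicate for every method, preserving the paired
comparison; the drop count is attached to the table. Efficiency is
scale-invariant (rescaling $y$ multiplies every MSPE by the square) and
the reference row is exactly 1 by construction.

## Numerical choices worth knowing

* $1/n$ standardization (see above); zero-variance columns are excluded
  from $\lambda_{\max}$ with a warning and get zero coefficients.
* A constant response is refused (`degenerate response`): there is
  nothing to threshold.
* CV ties resolve to the largest penalty (parsimony); fold assignment
  is a seeded random partition shared across a replicate's methods.
* LARS excludes from its step-length search any candidate already tied
  with the active correlation maximum (the tied ratios are 0/0 noise);
  tied candidates are proposed as entrants on the next iteration, and
  an entrant whose Gram column is numerically singular is dropped with
  a warning rather than entered.
* Ensemble member failures are excluded from the average; more than 10%
  failures abort the fit.
* All randomness flows from explicit seeds through deterministic child
  seeds — same seed, bit-identical dataset, table and CSV output; no
  global RNG state is consumed or leaked.

## Problem sizes used by the tests and the acceptance script

The full study grid (M = 2000 replicates, B = 250 members, 28 methods,
$p = 1000$) is a cluster-scale computation. The package's own checks
reproduce single cells of it at reduced replication, a deliberate
design choice sized for one CPU: the test suite uses M = 14–25
replicates with B = 30–40 members for the efficiency cells (tolerances
$\max(0.03, 3\,\mathrm{SE})$, so they widen honestly with the reduced
M), and `scripts/acceptance.R` uses M = 40 (complexity 0.15) and
M = 16 (complexity 0.30) with B = 50 for trimmed ensembles and B = 20
for cross-validated approach-1 ensembles (whose members each run a full
10-fold CV, the dominant cost). At these scales the Monte-Carlo SE of a
mean efficiency is 0.01–0.04. The reduced B biases ensemble efficiency
slightly *downward* (the un-removed $(1-\rho)\sigma^2/B$ term), bounded
and small because members are substantially correlated.

## What passing checks do and do not show

The simulation presets generate Gaussian covariates with homogeneous
pairwise correlation, a single contiguous signal block, and
near-noiseless strong-signal regimes. Real expression data have
heavy-tailed values, block- and network-structured correlation,
scattered signals and lower signal-to-noise. Agreement with the
published efficiency cells under the presets therefore validates the
*machinery* (solvers, subspace schemes, trimming, the evaluation
protocol), not a claim that ensembles beat CV lasso on any particular
real dataset — on real data the answer depends on the complexity
regime, and the fixed-design protocol exists precisely to measure it.

## Known limitations

* Gaussian linear regression only; no GLM families, no inference on
  coefficients.
* SCAD solutions are stationary points of a nonconvex objective;
  different warm-start paths could reach different points.
* The elastic net inherits glmnet's internal response standardization,
  so its ridge component is parametrized in units of $\mathrm{sd}(y)$;
  coefficients for $\alpha < 1$ are glmnet's, not the textbook
  objective's (identical predictions at $\alpha = 1$).
* The LARS-by-steps convention for "a path of 100 values" is a declared
  mapping, not canonical; `CVLARS` cross-validates the fraction index.
* Replicates run serially; the per-replicate child-seed design makes
  the results independent of any future parallel execution order.
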