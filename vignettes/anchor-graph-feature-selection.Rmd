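---
title: "Multi-modal feature selection with anchor graphs: model, algorithm and design notes"
author: "anchorFS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal feature selection with anchor graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorFS)
```

## The model

anchorFS selects features jointly across several blocks ("modalities")
of numeric measurements on the same subjects — the motivating setting
is tabular neuroimaging panels, e.g. regional MRI volumes, regional PET
uptake and CSF biomarkers for two diagnostic groups. With blocks
$X_v \in \mathbb{R}^{n \times d_v}$, one-hot labels
$Y \in \mathbb{R}^{k \times n}$, per-modality weights
$W_v \in \mathbb{R}^{d_v \times k}$, a shared bias $b$, and a
nonnegative feature-weight vector $\theta$ on the probability simplex
($\theta^\top \mathbf{1}_d = 1$, $d = \sum_v d_v$), the fitted
objective is

$$
\min_{W, b, \theta}\;
\Big\lVert \textstyle\sum_v W_v^\top \Theta_v X_v^\top + b\mathbf{1}^\top - Y \Big\rVert_F^2
+ \alpha \sum_v \lVert W_v \rVert_{2,1}
+ \beta \sum_v \operatorname{tr}\!\big(W_v^\top X_v^\top (I - B_vB_v^\top) X_v W_v\big)
$$

* **Row sparsity.** $\lVert W_v\rVert_{2,1} = \sum_i \lVert w_{vi}\rVert_2$
  zeroes whole rows, i.e. eliminates whole features. Internally the
  smoothed form $\sum_i \sqrt{w_i^\top w_i + \varepsilon}$ is used
  everywhere (objective and updates), so the reweighted update
  literally minimizes the recorded objective and descent is exact, not
  asymptotic.
* **Anchor graph.** Per modality, $m \ll n$ anchor points are drawn
  from the samples; each sample is connected to its $k$ nearest
  anchors with the closed-form weights
  $z_{ij} = (d_{i,k+1} - d_{ij}) / (k\,d_{i,k+1} - \sum_{j'\le k} d_{ij'})$
  ($d_{ij}$ = squared Euclidean distance), giving a row-stochastic,
  $k$-sparse affinity $Z$. The implied sample similarity
  $S = Z\Delta^{-1}Z^\top$ (with $\Delta = \operatorname{diag}$ of
  column sums) is row-stochastic, so its degree matrix is the identity
  and the Laplacian is $I - BB^\top$ with $B = Z\Delta^{-1/2}$. All
  Laplacian quadratic forms are computed as
  $\lVert M\rVert_F^2 - \lVert B^\top M\rVert_F^2$; nothing
  $n \times n$ is ever materialized.
* **Feature and modality weights.** The simplex constraint forces
  $\theta$ to allocate a unit budget across all $d$ features;
  within-modality sums of $\theta$ are reported as modality
  importances. This per-feature reading is the only one under which
  the $\theta$-step's algebra (a quadratic form via the diagonal
  congruence identity $\operatorname{tr}(ABAC) = a^\top(B^\top\!\circ C)a$)
  type-checks.

## The algorithm

`agfsFit()` initializes $\theta = 1/d$, $W = 0$, $b = 0$ and sweeps:

1. closed-form bias $b = \tfrac1n (Y\mathbf{1} - W^\top\Theta X^\top\mathbf{1})$;
2. for each modality, recompute the reweighting diagonal
   $N_{v,ii} = 1/(2\sqrt{w_i^\top w_i + \varepsilon})$ from the current
   $W_v$, then solve the linear system
   $(\Theta_v X_v^\top X_v \Theta_v + \alpha N_v + \beta X_v^\top(I-BB^\top)_vX_v)\,W_v = \Theta_v X_v^\top(\tilde Y^\top - \mathbf{1}b^\top)$;
3. the $\theta$-step: substituting the optimal bias turns the residual
   into a centered form with $H = I - \tfrac1n\mathbf{1}\mathbf{1}^\top$,
   and the trace identity reduces it to the simplex quadratic program
   $\min_\theta \theta^\top Q\theta - \theta^\top s$ with
   $Q = (X^\top H X) \circ (WW^\top)$,
   $s = \operatorname{diag}(2X^\top H Y^\top W^\top)$ — convex, since a
   Hadamard product of positive semidefinite matrices is positive
   semidefinite;
4. a final bias refresh, so the recorded objective is the
   bias-optimal one.

Under the default `coupling = "additive"` every step minimizes the same
concatenated-residual objective over one block of variables, and the
quadratic surrogate in step 2 majorizes the smoothed $\ell_{2,1}$ term,
so the recorded history is provably non-increasing; the fit *errors* if
it ever increases beyond relative 1e-6. `coupling = "independent"`
instead fits $Y$ separately per modality in steps 1–2, mirroring
per-modality update equations as printed in the multi-modal sparse
regression literature; the two couplings differ (they disagree already
on the residual definition), and only the additive one carries the
descent guarantee. Iteration stops when
$|obj(t{+}1) - obj(t)|/obj(t) \le$ `outerTol` (default 1e-5) or after
`maxOuterIters` (default 100) sweeps.

### The simplex solver

The $\theta$-step is solved by an augmented Lagrangian scheme with a
slack split $u = \theta$, $u \ge 0$: alternately
$\theta = E^{-1}g$ with $E = 2Q + \mu I + \mu\mathbf{1}\mathbf{1}^\top$,
$g = \mu u + \mu\mathbf{1} - \lambda_2\mathbf{1} - \lambda_1 + s$, and
$u = \max(\theta + \lambda_1/\mu,\, 0)$, followed by multiplier
updates. One symmetric eigendecomposition of $2Q$ plus a
Sherman–Morrison rank-one update makes every inner solve $O(d^2)$.

Three numerical choices here are load-bearing and were validated
against independent oracles (a long-run projected-gradient solver and,
for $d = 3$, brute-force simplex grids):

* **Scale normalization.** $(Q, s)$ are jointly divided by
  $\max(1, \max|Q|, \max|s|)$ — the minimizer is invariant — so the
  penalty $\mu$ is measured in units of the problem's curvature.
* **No penalty growth by default** (`muMax = mu0 = 1`). Once $\mu$
  exceeds the curvature, each multiplier step moves the iterate by
  $O(1/\mu)$ and the solver freezes at a feasible but suboptimal
  point; with the penalty held at the curvature scale the iteration
  converges linearly to high accuracy. A growth factor `rho` remains
  available.
* **KKT-based stopping.** Primal feasibility
  ($\max(\lVert\theta-u\rVert_\infty, |\theta^\top\mathbf{1}-1|) \le$
  `almTol`) alone is insufficient: the stationarity residual of the
  $\theta$-solve is $\mu(\theta - u)$, so at large $\mu$ feasibility
  can hold far from the optimum. The solver additionally requires a
  small simplex KKT error (gradient constant on the support, nowhere
  smaller off it, in min-form complementarity). On degenerate programs
  — after strong shrinkage most weight rows are $\approx 0$ and $Q$ is
  flat in most coordinates — the KKT test can stall; the solver then
  returns its best feasible iterate once that point's Frank–Wolfe gap
  (a rigorous upper bound on the attainable objective improvement)
  falls below $\sqrt{\texttt{almTol}}$ relative. Tight programs still
  exit through the KKT test at ~1e-6 accuracy in $\theta$.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `alpha` | 1e-4 | $\ell_{2,1}$ strength. Because $\theta$ spreads a unit budget over $d$ features, the data term carries an implicit $1/d^2$ scale; for $d \approx 190$ useful values are around 1e-4, far below what an unweighted $\ell_{2,1}$ regression would use. Larger values push the $\theta$-program into its linear regime and collapse the weight budget onto one feature. Tune over `alphaBetaGrid()` when in doubt. |
| `beta` | 0 | Graph-smoothness strength. Off by default: when only a minority of features carries class signal the anchor graph reflects mostly noise coordinates and its Laplacian acts as label-agnostic shrinkage. Enable and tune it when most features are expected to carry sample structure. |
| `epsilon` | 1e-8 | $\ell_{2,1}$ smoothing; keeps the reweighting finite at zero rows. |
| `mAnchors` | auto | $\min(4\lceil\sqrt n\rceil, n)$ anchors per modality. |
| `kNN` | 5 | nearest anchors per sample; must be $\le m-1$ so the $(k{+}1)$-th distance exists. |
| `outerTol` | 1e-5 | relative objective-change stopping rule. |
| `scale` | TRUE | z-score each column before graph construction and fitting; modalities of wildly different native scales (90-dimensional imaging vs 3 CSF assays) share one $\alpha$, which is meaningless without it. |

The grid helper `alphaBetaGrid()` returns
$\{10^{-3}, 10^{-2}, 10^{-1}, 1, 10, 10^2, 10^3\}$, the customary
log-spaced range for both penalties.

## The synthetic-data generator

`simulateMultiModal()` emulates the shape of a two-group multi-modal
biomarker study: defaults are n = 200 subjects, modality dimensions
(93, 93, 3), balanced binary classes (remainder samples to the first
class, order shuffled under the seed), independent Gaussian noise per
feature, and a planted informative subset per modality — defaults
(10, 10, 1) — whose class-conditional means are shifted by
`effectSize × modalityStrength[v] × noiseSD` (earlier classes higher).
Modality strength (default 0.4/0.4/0.2) multiplies the *signal*, not
the noise, so recovered $\theta$ mass is interpretable as signal
share. The additive Gaussian mean-shift design is the simplest model
under which row-sparse regression provably recovers support, which is
exactly what makes it a useful oracle: the generator returns the
planted index sets, and the test suite scores rankings against them.

What it does **not** emulate: correlated features (real ROI volumes
are strongly dependent), site/scanner effects, non-Gaussian marginals,
longitudinal visits, or label noise. Passing the bundled tests
therefore demonstrates correctness of the optimization and selection
machinery under the stated model, not clinical performance on real
cohorts.

## Evaluation harness

`crossValidate()` implements stratified k-fold (default 10)
cross-validation in which *everything* — z-scoring statistics, anchor
graphs, the selector fit, the feature ranking — is computed on
training rows only; the top `nSelect` features feed a linear SVM
(`e1071::svm`, consumed through a narrow trainer contract so any
classifier returning predictions and scores can be substituted).
Metrics are accuracy, sensitivity, specificity and Mann–Whitney AUC
(midranks, ties = ½); with a single-class truth the undefined metrics
are `NA`, never 0. `gridSearch()` reports the full α/β table and never
silently picks the test-best cell; fold splits are stratified because
class counts near 50/50 on ~100 subjects make plain folds fragile.

## Numerical and design choices

* Distance ties in the affinity sort break by anchor index (stable
  order); rows whose $k{+}1$ nearest distances are all equal fall back
  to uniform $1/k$ weights with a warning; anchors receiving zero
  affinity mass are dropped before normalization, with a warning.
* The anchor regularizer of the graph-learning objective is absorbed
  into the closed form by choosing it per row from the $(k{+}1)$-th
  neighbor distance, so `kNN` is the only graph parameter a user sets.
* Feature scores default to `theta_weighted`
  ($\theta_i \lVert w_i\rVert_2$): both factors are learned
  importances. `row_norm` is kept for ablation. Ties in ranking break
  by smaller index.
* Initialization is deterministic ($\theta$ uniform, $W=0$, $b=0$);
  the seed affects only data generation, anchor sampling and fold
  splits.
* The linear systems in step 2 are always solved, never inverted; a
  singular system (possible only in exotic limits) falls back to a
  least-squares solution with a warning.
* Model files are JSON with 17 significant digits (doubles round-trip
  exactly) and an embedded schema version.

## Problem sizes

The test suite and the acceptance script run the reference
configuration (n = 200, d = 189) for single fits, 20-seed recovery
studies and one 10-fold cross-validation, plus many small randomized
instances (n ≤ 20) for the algebraic contracts; a full run takes a few
minutes on one CPU. Larger problems are limited mainly by the $O(d^2)$
inner iteration and the $O(d^3)$ eigendecomposition per $\theta$-step.

## Known limitations

* The bilinear $\theta \otimes W$ parameterization is jointly
  non-convex; block descent guarantees monotone convergence, not a
  global optimum, and the $\theta$ allocation can be winner-take-all
  when regularization is strong.
* Multi-class labels (k > 2) are supported by the algebra but the
  evaluation harness is binary.
* `coupling = "independent"` reproduces per-modality printed update
  equations but has no descent guarantee; use it for comparison only.
* Modality importance is a sum of per-feature weights, so a modality
  with many weak features can outrank one strong feature; interpret
  together with the per-feature ranking.
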