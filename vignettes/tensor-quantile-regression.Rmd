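---
title: "Tensor quantile regression by smoothed block relaxation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tensor quantile regression by smoothed block relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tqreg)
```

## The model

`tqreg` fits a linear quantile regression for a scalar response $Y$ on
scalar covariates $x \in \mathbb{R}^{p_0}$ and one tensor-valued covariate
$Z \in \mathbb{R}^{p_1 \times \cdots \times p_q}$:

$$Q_\tau(Y \mid x, Z) = \alpha + x^\top\beta + \langle Z, \Gamma\rangle,$$

where $Q_\tau$ is the conditional $\tau$-quantile and
$\langle Z,\Gamma\rangle = (\mathrm{vec}\,Z)^\top \mathrm{vec}\,\Gamma$. The
tensor effect $\Gamma$ would carry $\prod_j p_j$ free parameters — 4096 for
a modest $64\times 64$ image — so it is constrained to a Tucker
decomposition of rank $(R_1,\ldots,R_q)$,

$$\Gamma = \sum_{r_1=1}^{R_1}\cdots\sum_{r_q=1}^{R_q}
  \lambda_{r_1\ldots r_q}\,
  \gamma^{(1)}_{r_1}\circ\cdots\circ\gamma^{(q)}_{r_q}
  = [\![\Lambda; \Gamma^{(1)},\ldots,\Gamma^{(q)}]\!],$$

with core tensor $\Lambda$ and factor matrices
$\Gamma^{(j)} \in \mathbb{R}^{p_j\times R_j}$. Quantile regression is the
natural choice when responses are skewed, heavy-tailed, or
heteroskedastic — conditions under which least-squares tensor regression
degrades badly (see the Cauchy comparison below).

The decomposition makes the objective nonconvex jointly, but *linear in
each parameter block* when the others are fixed: the identities

$$\mathrm{vec}\,\Gamma = \Big(\textstyle\bigotimes_{k=q}^{1}
  \Gamma^{(k)}\Big)\,\mathrm{vec}\,\Lambda,
\qquad
\langle Z,\Gamma\rangle = \Big\langle Z_{(j)}\,\Gamma^{\otimes}_{-j}\,
  \Lambda_{(j)}^\top,\ \Gamma^{(j)}\Big\rangle$$

(with $\Gamma^{\otimes}_{-j}$ the Kronecker chain skipping mode $j$ and
$A_{(j)}$ the mode-$j$ matricization) supply an exact design matrix per
block. Both identities are verified numerically in the test suite to
1e-10 on random instances.

A layout convention the package fixes once: vectorization is
mode-1-fastest (R's native column-major order) and matricization follows
the Kolda–Bader column ordering. Under this convention the reverse-order
Kronecker chain identity above holds exactly; the Jacobians used by the
score and information are *derived from this convention* and validated
against central finite differences rather than transcribed from any
printed ordering, since vec-layout conventions differ across the tensor
literature.

## Smoothing the check loss

The check loss $\rho_\tau(u) = (\tau - 1\{u<0\})u$ is not differentiable,
so gradient methods cannot be applied directly. The estimator minimizes
the generalized Huber surrogate

$$H_{\tau,\nu}(u) =
\begin{cases}
u(\tau-1) - (\tau-1)^2\nu/2, & u < (\tau-1)\nu\\
u^2/(2\nu), & (\tau-1)\nu \le u < \tau\nu\\
u\tau - \tau^2\nu/2, & u \ge \tau\nu,
\end{cases}$$

which is convex, $C^1$, and converges uniformly to $\rho_\tau$ with gap at
most $\nu\max(\tau,1-\tau)^2/2$. The smoothing parameter is annealed along
a geometric schedule $\nu_{k+1} = \text{decay}\cdot\nu_k$, each stage
warm-starting from the previous solution.

Schedule defaults, with rationale (no canonical values exist for this
smoother and the residual-dependent update rules remain future work):

* `nu0 = max(1, IQR(y - eta0))` at the initial estimate — the first stage
  should be quadratic over the bulk of the residuals, and the IQR adapts
  that width to the data scale;
* `decay = 0.1` — one decade per stage keeps the schedule short (five to
  eight stages in practice) while each warm start stays inside the
  contraction region of the next stage;
* `nu_min = 1e-4` — at this width the uniform gap is below
  $1.25\times10^{-5}$, far below the statistical error at the sample sizes
  the package targets.

## The block-relaxation algorithm

Each sweep updates the blocks in the fixed cyclic order
$(\alpha,\beta) \to \Lambda \to \Gamma^{(1)} \to \cdots \to \Gamma^{(q)}$
(free-steering orders are possible in principle but have weaker
convergence theory). A block update runs gradient descent on the block's
convex smoothed subproblem with Barzilai–Borwein step sizes, alternating
the two secant formulas, under an Armijo backtracking safeguard. Two
implementation rules keep the descent property exact rather than
approximate:

* an inner step is accepted only if it strictly decreases the block
  objective;
* the updated block is accepted only if the *full* penalized objective —
  recomputed by the single canonical evaluation path — does not increase;
  otherwise the old block is kept.

Consequently the recorded loss path is non-increasing across every block
update within each smoothing stage, with zero tolerance; this is asserted
on every fit in the test suite, as it is the premise of the global
convergence argument for block relaxation. A stage terminates when the
relative objective change over a sweep falls below `rel_tol = 1e-4` (the
0.01 % rule) — applied to the *penalized* objective, so that the monitored
quantity is the same one the monotonicity guarantee covers.

Initialization is random: factor entries iid $N(0,1)/\sqrt{p_j}$, a zero
core, the intercept at the sample $\tau$-quantile, followed by one core
update before the first sweep so the random factors acquire a data-driven
scale. Because the joint problem is nonconvex, `n_restarts` (default 3)
independent initializations are fitted from distinct sub-seeds and the
best final objective wins; ties are impossible in practice, and the first
minimum is kept if they occur. The returned effect is canonicalized —
unit-norm factor columns, sign fixed by the largest-magnitude entry,
scales absorbed into the core — which removes the scaling part of the
Tucker indeterminacy cheaply and deterministically.

The inner iteration cap (`inner_max_iter`, default 200) rarely binds near
convergence because the gradient tolerance `1e-8` per parameter triggers
first. For cross-validation grids, where dozens of fits are needed and
each fold only has to rank penalty weights, a much smaller cap (15–25)
with `max_sweeps` 10–15 loses almost nothing: block relaxation tolerates
inexact inner solves, and the monotone-acceptance rule keeps even an
inexact sweep a descent step.

### Numerical edge cases

Residuals landing exactly on a Huber knot take the closed linear-piece
derivative; the pieces agree there, so this is only a tie-break. A zero
factor column cannot be canonicalized and raises an error rather than
silently producing `NaN`. A constant response triggers a degenerate-fit
warning. A Barzilai–Borwein step that is nonpositive or nonfinite falls
back to the previous step length, and backtracking halves at most 40
times before the update gives up and returns the entry state.

## Penalties through the composed effect

Penalties act on the composed tensor $\Gamma$, never on $\Lambda$ or the
$\Gamma^{(j)}$ directly and never on $(\alpha,\beta)$ — penalizing the
decomposition components would make the penalty depend on an arbitrary
internal parameterization, while spatial penalties such as the fused lasso
are only meaningful on the effect map itself. Gradients reach the
decomposition parameters by the chain rule:
$\nabla_{\mathrm{vec}\Lambda} J = \Gamma^{\otimes\top}
\mathrm{vec}(\partial J/\partial\Gamma)$ and
$\nabla_{\mathrm{vec}\Gamma^{(j)}} J = \mathrm{vec}[(\partial
J/\partial\Gamma)_{(j)}\,\Gamma^{\otimes}_{-j}\Lambda_{(j)}^\top]$.

The absolute value inside each penalty is smoothed as
$|u| \approx 2H_{0.5,\nu}(u)$ with the *same* $\nu$ as the loss by default
(`smooth_with_nu = TRUE`), so loss and penalty converge uniformly
together along the schedule and the convergence argument applies to the
penalized objective as a whole; a fixed `nu_pen` is available when the
penalty should stay smooth while the loss anneals.

Two families are built in. The elementwise lasso sums $2H_{0.5,\nu}$ over
cells. The fused lasso sums smoothed absolute differences over an
adjacency graph; `grid_adjacency()` builds the order-3 grid geometry with
vertical and horizontal neighbour terms per mode-1 slice, optional
wraparound in the last mode (for cyclic surface parameterizations), and no
terms across mode-1 slices, so anatomically disjoint structures stacked
along mode 1 are never fused together. When the last mode has length two,
the wraparound duplicates a cell pair; the defining double sum is followed
literally (both terms counted) so the penalty value is reproducible from
the formula. Custom geometries load from a two-column edge-list CSV.

## Score, information, identifiability

For the smoothed model the per-observation score stacks
$-H'_{\tau,\nu}(y-\eta)\,d$ with
$d = [\,1 \mid x \mid \Gamma^{\otimes\top}\mathrm{vec}Z \mid
\mathrm{vec}(Z_{(j)}\Gamma^{\otimes}_{-j}\Lambda_{(j)}^\top),\ j=1..q\,]$,
and the empirical information is
$I_N = n^{-1}\sum_i H'^2 d_i d_i^\top$. $I_N$ is always singular along the
$\sum_j R_j^2$ tangent directions of the Tucker reparameterization group
($\Gamma^{(j)} \to \Gamma^{(j)}M$, $\Lambda_{(j)} \to M^{-1}\Lambda_{(j)}$);
`is_locally_identifiable()` therefore projects $I_N$ onto the orthogonal
complement of those directions and tests the smallest remaining eigenvalue
against a relative threshold. A factorization with duplicated factor
columns fails the check; a generic random model passes.

The test suite checks first-order optimality of fits (score norm vanishing
at the fitted optimum) at smoothing level $\nu = 0.1$: at much smaller
$\nu$ the subproblem curvature scales like $1/\nu$ and a first-order
method verifies the 0.01 % objective rule long before machine-level
stationarity, so a gradient-norm assertion there would measure solver
conditioning, not correctness.

## Model selection

Rank is selected by BIC on unpenalized fits:
$\mathrm{BIC} = 2n\bar L + \mathrm{df}\log n$ with $\bar L$ the mean
*unsmoothed* check loss at the final estimate and
$\mathrm{df} = 1 + p_0 + \prod_j R_j + \sum_j p_j R_j - \sum_j R_j^2$, the
Tucker parameter count net of the reparameterization indeterminacy.
Effective degrees of freedom for penalized quantile fits are an open
research question, so the penalty weight $\lambda$ is tuned by $K$-fold
cross-validation (default $K = 5$) instead, scoring held-out mean check
loss at $\tau$ — the quantity the model optimizes, rather than MAE, which
is reported separately by `evaluate_fit()`. Ties go to the smaller
$\lambda$.

## What the simulation suite emulates

`simulate_tqr()` reproduces a standard scalar-on-image design: binary
$p\times p$ signal tensors (square, cross, disk, triangle, five-pointed
star) with entries in $\{0,1\}$, covariate entries iid standard normal,
$\beta = (1,\ldots,5)^\top$, and errors from normal, t, Cauchy, or
$\chi^2$ families scaled to a target signal-to-noise ratio. Defaults are
$p = 64$, $n_{\text{train}} = 2000$, SNR 3, $\tau = 0.5$.

Choices the design leaves open, fixed here once:

* **SNR definition.** $\mathrm{SNR} = \mathrm{sd}(\eta)/\mathrm{sd}
  (\varepsilon)$. The Cauchy has no variance, so its spread is matched
  through the interquartile range: the scaled Cauchy gets the same IQR as
  a normal error would have at that SNR ($s = \mathrm{sd}(\eta)/(\mathrm{snr}
  \cdot 2/(2\Phi^{-1}(0.75)))$). Absolute error metrics depend directly on
  this convention.
* **Centering.** Skewed families are median-centered (χ² shifted by its
  median) so the $\tau = 0.5$ model is correctly specified; for other
  $\tau$ the intercept absorbs the offset.
* **Degrees of freedom.** t and χ² default to 3 — heavy-tailed and
  clearly skewed, respectively, while keeping the t variance finite.
* **Shapes.** Only the star needs rasterization; it is the even-odd fill
  of the ten-vertex outline polygon (outer radius $0.45p$). The cross is
  exactly a rank-2 tensor, making it the natural rank-2 truth.

`make_surface_fixture()` builds the order-3 analogue of a reduced
two-hemisphere surface grid ($2\times 75\times 50$ by default): a
piecewise-constant effect with a few rectangular patches per mode-1 block,
one wrapping across the mode-3 seam — the geometry the fused lasso is
designed for. It is a synthetic stand-in: it emulates the shape, sparsity
and wraparound topology of surface-derived features, not their correlation
structure.

What passing these simulations does *not* show: real imaging covariates
are spatially correlated and the tensor entries here are independent, so
recovery at a given $n$ is optimistic relative to real data;
piecewise-constant truth favors the fused lasso by construction; and all
error families here are iid, so heteroskedasticity robustness is not
exercised.

## Problem sizes used in the tests

The test suite runs desk-scale versions of the study: consistency on
$16\times16$ rank-1 truth with $n \in \{250, 500, 1000\}$ (5 seeds);
loss-robustness on a $32\times32$ cross at $n = 1000$, SNR 3 (5 seeds,
quantile vs. squared loss under normal and Cauchy errors); rank U-shape on
$16\times16$ at $n = 400$ for $R \in 1..5$; lasso cross-validation on a
$16\times16$ star at $n = 150$, SNR 2; fused lasso on a
$2\times12\times10$ fixture at $n = 300$. These sizes preserve each
qualitative contrast (error decreasing in $n$, Cauchy superiority,
interior rank optimum, background suppression) at a few minutes of total
runtime; absolute error values at these sizes are naturally larger than at
the full $64\times64$, $n = 2000$ scale.

## Known limitations

One tensor covariate per model (stack along mode 1 to combine several
aligned features); convex penalties only (SCAD/MCP would need a different
majorization); no standard-error or interval output — the asymptotic
normality of the estimator is exercised through recovery properties, not
exposed as inference; dense tensors only.
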