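---
title: "Power for stepped-wedge trials under GLMMs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power for stepped-wedge trials under GLMMs: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdglmm)
```

## The problem

A stepped-wedge design (SWD) is a cluster-randomized crossover design in
which every cluster starts on control and crosses over to the intervention
at a randomized, staggered time, staying on intervention thereafter.  The
design variables are the number of sequences $S$ (groups sharing a
crossover time), periods $T$, clusters per sequence, optionally a second
clustering level (e.g. care providers within a clinic), and the number of
individuals sampled per cell.  `swdglmm` computes power and sample size for
cross-sectional SWDs when the planned analysis is a generalized linear
mixed model (GLMM) on the natural link scale — identity for normal
outcomes, logit for binary, log for counts — rather than a normal
approximation of a risk or rate difference.

## Model

For cluster $j$ with outcomes $Y_j$, fixed design $X_j$ (intercept, time
effects, intervention indicator last) and random design $Z_j$,

$$E[Y_j \mid b_j] = h(X_j\beta + Z_j b_j), \qquad
  \mathrm{Var}[Y_{ij} \mid b_j] = \phi\, a_{ij}\, v(\mu_{ij}),$$

with $b_j \sim N(0, D)$ independent across clusters, $g = h^{-1}$ the link,
$\phi$ the dispersion ($\sigma^2$ for normal outcomes, 1 otherwise),
$a_{ij}$ a known prior weight, and $v(\cdot)$ the variance function (1,
$\mu(1-\mu)$, or $\mu$).  Supported random components are a cluster
intercept, a cluster-by-treatment interaction, iid cluster-by-period
effects (one indicator column per period, including the first), and
subcluster intercepts; they are uncorrelated by default, and a full
positive-semidefinite $D$ may be supplied instead.

## Variance approximation

The covariance of the estimated coefficients is approximated by the
penalized quasi-likelihood / Laplace expression

$$\mathrm{Var}(\hat\beta) = \Big(\sum_j X_j^\top V_j^{-1} X_j\Big)^{-1},
  \qquad V_j = W_j + Z_j D Z_j^\top,$$

where $W_j$ is diagonal with entries
$w_i = \phi\, a_i\, v(\mu_i)\, g'(\mu_i)^2$ evaluated with the random
effects plugged in at their prior mode of zero, so that $\mu_i =
h(x_i^\top\beta)$.  For the identity link the weights do not involve
$\beta$ and the approximation is exact (the classical weighted-least-squares
setting for normal SWD outcomes); for logit and log links it is an
approximation whose quality is the subject of the Monte-Carlo harness
below.

Two exact reductions make the computation essentially instantaneous:

* **Exchangeable-row aggregation.**  Individuals in the same
  subcluster-period cell share the same rows of $X$, $Z$, and the same
  $\eta$, so $c$ identical rows collapse to one row with working variance
  $w/c$; $X^\top V^{-1} X$ is unchanged.  A two-level clinic block with 840
  individuals becomes 210 cell rows.
* **Woodbury identity.**  $V^{-1}$ is applied through
  $W^{-1} - W^{-1} Z L (I + L^\top Z^\top W^{-1} Z L)^{-1} L^\top Z^\top
  W^{-1}$ with $D = LL^\top$, inverting only an $r \times r$ core
  ($r \le q$).  Factoring through $L$ keeps the identity valid when some
  variance components are zero.  Equivalence with direct inversion is
  enforced in the test suite at $10^{-8}$ relative Frobenius error.

Clusters within a sequence are identical by construction, so one
representative block per sequence is computed and its information scaled by
the cluster count — also exact.

## Power and sample size

With a two-sided level $\alpha$ test of $H_0: \beta_p = 0$,

$$\mathrm{Power} = \Phi\!\left(\frac{|\beta_p| -
  Z_{1-\alpha/2}\sqrt{V_0(\hat\beta_p)}}{\sqrt{V_a(\hat\beta_p)}}\right),$$

where $V_0$ and $V_a$ are the variances of $\hat\beta_p$ under the null and
alternative.  For non-identity links the weights depend on the mean model,
so the two differ.  The package's default recomputes the linear predictor
(and hence $W^0$) with $\beta_p = 0$ for $V_0$, holding every other
coefficient and all variance components at their alternative values; this
is the reading most faithful to the formula's distinct $V_0$ and $V_a$.
Because the convention is genuinely open, `null_variance = "alternative"`
reuses $V_a$ in both places.  The choice moves solved sample sizes by
roughly 5–10% in the bundled examples.  Note that a Wald test with the
model standard error evaluated at the MLE implicitly uses the
alternative-variance convention for its critical value; comparisons against
Wald rejection rates should therefore use `null_variance = "alternative"`.

The inverse problems — smallest cell size (`swd_solve_n()`) or smallest
equal allocation of clusters per sequence (`swd_solve_clusters()`) reaching
a target power — use exponential bracketing plus integer bisection.  Power
is monotone in both variables, but only up to a plateau: with a random
treatment (or period) effect the variance of $\hat\beta_p$ has a floor that
no amount of within-cluster sampling can push below, so an unreachable
target raises an error reporting the plateau power rather than silently
returning the cap.  Monotonicity is verified at the bracket endpoints and a
non-monotone trace aborts.  Totals from the cluster solver move in
multiples of the number of sequences because allocation is equal by
construction.

## Presets

Two application presets and two simulation presets ship with the package
(`swd_preset()`); all parameters are on the log-odds scale.

* **`ept`** — a four-sequence, five-period roll-out across 24 counties
  (6 per sequence) with a binary outcome at baseline prevalence 0.08,
  categorical period effects $(-0.008, -0.08, -0.17, -0.11)$, intervention
  log odds ratio $-0.3$, cluster-intercept SD 0.2, and iid per-period SDs
  0.12.  The intercept is $g(0.08)$, anchoring the stated prevalence to the
  all-control first period.
* **`lire`** — a five-sequence, six-period design over 100 clinics
  (20 per sequence) with 35 primary-care providers per clinic and a binary
  outcome; linear time, intervention log odds ratio $-0.055$, clinic SD
  0.011, clinic-level treatment SD 0.0054, provider SD 0.0015.  Time is
  coded as the period number $1..6$ with slope $-0.124$ and intercept
  $g(0.19)$: this mirrors the convention of the fitted analysis model these
  coefficients come from, where "prevalence 0.19" is the inverse-logit of
  the regression intercept (the extrapolated period-zero value), not the
  period-one mean.  A zero-based coding with the same intercept would make
  every period about one slope-step more prevalent and shifts the solved
  clinic totals down by some 10 clinics.
* **`sim_model1` / `sim_model2`** — the validation-grid design (3
  sequences, 4 periods) with, respectively, cluster intercept + cluster
  treatment effect, and cluster intercept + iid cluster period effects.
  Grid defaults are the moderate point: 8 clusters per sequence, 100
  individuals per cluster-period, prevalence 0.12, period effects all 0.1,
  effect 0.2, all random-effect SDs 0.05; alternatives (4 or 12 clusters,
  cells of 20 or 50, prevalences 0.03 or 0.43, SDs 0.1) are reached through
  the preset arguments.

## Monte-Carlo validation harness

`swd_simulate()` draws data from exactly the model above: $b_j \sim N(0,
D)$ per cluster, then family sampling at $h(X\beta + Zb)$.  It emulates a
balanced cross-sectional design with new individuals each period and
cluster sizes constant over time; it does not emulate unequal cluster
sizes, attrition, cohort correlation, or time-varying confounding, so
agreement between the analytic and empirical variance says nothing about
those features of real trials.

`swd_fit()` maximizes the exact marginal likelihood (not PQL) after
collapsing observations to cell sufficient statistics: adaptive
Gauss–Hermite quadrature (9 nodes by default) for one random effect per
cluster, a Laplace approximation with vectorized Newton mode-finding for
two.  Structures with more than two random columns per cluster (e.g. the
per-period random effects of `sim_model2`, or the two-level `lire`
structure) are beyond the internal fitter; `swd_mc_validate()` accepts any
external fitter honouring the small contract (`coef` with treatment last,
`se_treatment`, `converged`, `boundary`).  Wald rejection at level $\alpha$
defines empirical power.

Two conventions deserve note.  First, non-converged replicates are
excluded from all tallies.  Fits whose variance estimates collapse to the
zero boundary (singular fits) are counted and reported but *kept* by
default: with generating SDs as small as 0.05 the boundary rate approaches
80%, and conditioning the replicate sample on the variance-component
estimate visibly biases the empirical variance of $\hat\beta_p$ (in our
checks the analytic/empirical ratio moved from 0.94 to 0.78 when singular
fits were dropped).  `exclude_boundary = TRUE` restores the stricter rule.
Second, replicate seeds are drawn once from the master seed, so any
subset of replicates is reproducible.

The bundled validation runs use 500 replicates at the moderate grid point
(variance ratio within 10% of 1; empirical Wald power within the binomial
95% band of the matched analytic value) and 300 at the extreme corner
(4 clusters per sequence, cells of 20, prevalence 0.03), where the
approximation is expected to *understate* the variance — asserted
directionally, since the degradation there is qualitative.  These sizes
give Monte-Carlo error small enough for the stated bands while keeping the
default check suite to a few minutes.

## Numerical choices

* Symmetric positive-definite solves use Cholesky factorizations; the full
  inverse is formed only where requested.  $D$ is accepted when its
  smallest eigenvalue is $\ge -10^{-10}$ (relative); anything worse is an
  error, never silent jitter.
* A singular information matrix raises an "inestimable" error with rank
  diagnostics (the canonical example: one sequence, two periods,
  categorical time — the period dummy equals the treatment column).  The
  information condition number is reported and flagged beyond $10^{10}$.
* Working weights are validated: a linear predictor that drives a logit or
  log mean to its boundary is reported with the offending $\eta$.
* The fitter optimizes over log standard deviations with `nlminb`
  (relative tolerance $10^{-9}$), warm-starting the Newton inner loop from
  the previous outer evaluation; standard errors come from a
  central-difference Hessian of the marginal deviance.  Estimates with
  $|\hat\beta|$ beyond 15 on the link scale are treated as non-converged
  (separation).

## Limitations

* Cross-sectional designs only: no cohort (repeated-measures) random
  effects, no exponentially decaying within-cluster correlation, and no
  cluster sizes that vary across periods within a cluster.
* The four canonical family/link pairs only; no offsets and no covariates
  beyond time and treatment.
* The analytic variance is a plug-in Laplace approximation: with few small
  clusters and rare outcomes it understates the variance of the MLE, and
  sample sizes computed there inherit that optimism.  The Monte-Carlo
  harness exists precisely to check the regime of interest before a design
  is fixed.
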