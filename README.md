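# swdglmm

Analytic power and sample-size calculation for **stepped-wedge
cluster-randomized trials** with normal, binary, or count outcomes
modelled on their natural link scale under generalized linear mixed models
(GLMMs) — for trial statisticians who want to explore many design options
without waiting on simulation.

In a stepped-wedge design all clusters start on control and cross over to
the intervention at randomized, staggered times.  The planned analysis is
a GLMM

```
E[Y_j | b_j] = h(X_j β + Z_j b_j),   Var[Y_ij | b_j] = φ a_ij v(μ_ij),
b_j ~ N(0, D),
```

with the intervention effect `β_p` as the last fixed-effect column.  The
package approximates the covariance of the estimated coefficients by the
penalized quasi-likelihood / Laplace expression

```
Var(β̂) = ( Σ_j X_jᵀ V_j⁻¹ X_j )⁻¹,   V_j = W_j + Z_j D Z_jᵀ,
```

with the diagonal working weights `w_i = φ a_i v(μ_i) g′(μ_i)²` evaluated
at random effects zero, and plugs the null and alternative variances into
the two-sided normal power formula

```
Power = Φ( (|β_p| − Z_{1−α/2} √V₀) / √V_a ).
```

Exchangeable individuals within a cell are collapsed exactly, and `V_j⁻¹`
is applied through the Woodbury identity, so even a two-level design with
hundreds of clinics evaluates in milliseconds.  A Monte-Carlo harness
(simulator + internal marginal-ML GLMM fitter) checks the approximation in
the regime of a planned trial.

## Worked example

Power of a four-sequence, five-period roll-out across 24 counties with a
binary outcome (baseline prevalence 8%, intervention log odds ratio −0.3,
cluster-intercept SD 0.2, per-period SDs 0.12), measuring 140 women per
county-period:

```r
library(swdglmm)
swd_power(swd_preset("ept"))
#> Stepped-wedge GLMM power (Laplace approximation)
#>   design: 4 sequences x 5 periods, 24 clusters, 140 per cell
#>   effect -0.3, alpha 0.05
#>   Var(beta_p): null 0.0105436, alternative 0.0117167
#>   power: 0.8192
```

`V₀` and `V_a` differ because the logit weights change when the effect is
set to zero; with 140 women per cluster-period the design has 82% power.
The smallest adequate cell size:

```r
swd_solve_n(swd_preset("ept"), target = 0.8)
#> Stepped-wedge sample-size solution
#>   variable: n_per_cell, target power 0.80 at alpha 0.05
#>   solution: 131 (achieved power 0.8000)
#>   individuals per cluster-period: 131
#>   search evaluations: 16
```

For a two-level design — 35 primary-care providers per clinic, clinic and
provider random intercepts plus a clinic-level random treatment effect —
solve for the total number of clinics (equal allocation over 5 sequences,
so totals move in steps of 5):

```r
des <- swd_preset("lire")
des$layout$n_per_cell <- 6     # 210 patients per clinic-period
swd_solve_clusters(des, target = 0.8)
#> Stepped-wedge sample-size solution
#>   variable: clusters_per_sequence, target power 0.80 at alpha 0.05
#>   solution: 28 (achieved power 0.8098)
#>   total clusters: 140 over 5 sequences
#>   search evaluations: 10
```

Custom designs are built from `swd_layout()` + `swd_model()`; power curves
come from `swd_power_curve()` (with a `plot()` method), and
`swd_mc_validate()` runs the simulation comparison for any supported
scenario.  A thin command-line wrapper is installed under
`inst/cli/swdglmm`:

```sh
Rscript inst/cli/swdglmm power --preset ept --format json
Rscript inst/cli/swdglmm samplesize --preset lire --solve-for clusters
```

See the vignette in `vignettes/swd-glmm-power.Rmd` for the model, the
approximation, the null-variance convention, and the validation harness.

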