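---
title: "Partitioning change in mean fitness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning change in mean fitness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical machinery of `asterpart`: the
life-history model, the mixed-model fit, the mapping to familial fitness,
the Price-equation partition, the synthetic-data generator, and the
numerical choices behind each. It is the design record for maintainers; the
README shows the user-facing workflow.

## The life-history model

Individual fitness in an annual plant is not a single measurement but the
end of a chain of conditional events: a planted seed germinates (or not),
a germinant survives to flower (or not), a flowering plant makes some
number of pods, and pods contain seeds. Modeling the final seed count
alone — zero-inflated, multimodal, wildly non-Gaussian — with a linear
model is hopeless. Instead each arrow of the chain gets a one-parameter
exponential family conditional on its predecessor:

* `Germ | planted ~ Bernoulli`,
* `Flower | Germ ~ Bernoulli`,
* `TotalPods | Flower ~ Poisson`,
* `Seeds | SamplePods ~ Poisson` with the sampled pod count as exposure.

The joint log-likelihood is `sum_j [x_j theta_j - x_p(j) c_j(theta_j)]`
with cumulants `log(1 + e^theta)` and `e^theta`. Structural zeros (a plant
that never germinated has zero everything downstream) contribute exactly
zero: the conditional family at sample size zero is degenerate, which is
the correct probability statement, not a missing-data fudge.

**Conditioning on the pod subsample.** When not every pod's seeds could be
counted, the number of pods sampled (`SamplePods`) is determined by the
measurement protocol, not by the plant. We therefore condition on it rather
than model it: the seed node becomes a Poisson regression with offset
`log(SamplePods)`, and the fitness scalar rescales seeds per sampled pod
back to the whole plant,

`W = mu_Seeds * mu_TotalPods / mu_SamplePods`,

which algebraically reduces to (seeds per sampled pod) × E\[TotalPods\] and
is therefore invariant to the subsampling rate. The alternative — modeling
`SamplePods` as a stochastic node — would add a nuisance parameter with no
effect on `W`; we document the choice and keep the graph configurable.

**Parameter scales.** Three scales matter. The conditional canonical scale
`theta` is where the likelihood is simple; the unconditional canonical
scale `phi_j = theta_j - sum_{k: p(k)=j} c_k(theta_k)` is where linear
modeling is done (effects on `phi` propagate coherently through the whole
chain); and the mean-value scale `xi_j = c_j'(theta_j)`,
`mu_j = xi_j mu_p(j)` is the measurement scale, expected count per seed
planted. The `phi -> theta` inversion is a backward recursion from the
leaves and is exact (round-trip identity well below 1e-10 in tests).
Canonical parameters are clipped at ±30 before exponentiation — an
overflow guard far outside any biologically attainable value (e^30 pods per
plant); a fit that touches the bound is flagged `boundary`.

## Fitting

With fixed effects only, the design `phi = M beta` (each node its own
coefficients) gives a concave log-likelihood, maximized by damped Fisher
scoring with backtracking line search: the score on the `phi` scale is
exactly `x - mu(phi)` and the expected information is `Var(x)`, computed by
the chain recursions `Var(x_j) = c_j'' mu_p(j) + xi_j^2 Var(x_p(j))` and
`Cov(x_j, x_a) = xi_j Cov(x_p(j), x_a)`. Convergence demands gradient
max-norm below 1e-8 (step norm 1e-10 as a secondary stop). Cells with no
successes (e.g. no germinants) drive the canonical parameter to the clip
bound; such fits return flagged boundary estimates rather than diverging
silently.

The sire random effect enters the unconditional canonical parameter of the
terminal seed node — the node whose parameter maps directly to fitness —
as `b_i ~ N(0, sigma2)`. Marginal likelihood is approximated by Laplace's
method:

`l_m(sigma2) = max_{beta, b} [ l(beta, b) - b'b / (2 sigma2) ]
  - 1/2 log det( sigma2 H_bb + I )`

where `H_bb` is the b-block of the expected information at the penalized
optimum. The inner problem is solved by penalized Fisher scoring over
`(beta, b)` jointly — profiling `beta` in the inner solve rather than the
outer search is the same device `lme4` uses; it ignores only the
(negligible) dependence of the log-determinant on `beta`, and on the seed
node's subproblem the result agrees with `lme4::glmer` to four decimals in
`sigma2` in the test suite. The outer problem is a one-dimensional
`optimize()` over `log(sigma2)`; an optimum below 1e-8, or a criterion no
better than the `sigma2 -> 0` limit, is mapped to an exact boundary zero,
at which the fit reproduces the fixed-effects estimates exactly and the
random effects are pinned at zero.

Dam (full-sib) effects are deliberately not modeled by default: basing
genetic inference on sires avoids confounding with maternal environmental
transmission, which is the standard rationale for paternal half-sib
designs. The random term is configurable (`aster_spec(random = ...)`) for
sensitivity analyses.

**Familial fitness and its covariance.** Lineage `i`'s fitness is the
fitness scalar evaluated at the reference cell's canonical parameters with
`b_i` added at the seed node. The reference covariate profile is the
average design row of the cohort (for the default intercept-only fit this
is just the cohort's own cell); it is overridable via `newdata`. The
covariance of the familial fitnesses comes from the delta method: a
central-difference Jacobian of the familial map times the inverse of the
penalized observed information for `(beta, b)`. At the `sigma2 = 0`
boundary the unpenalized joint information is singular (the random-effect
indicators are collinear with the intercept), and the correct limit —
infinite shrinkage — is to propagate fixed-effect uncertainty only.

**Va(W).** The additive genetic variance of fitness is mapped from the
canonical scale by 21-point Gauss–Hermite quadrature: push `N(0,
sigma2_hat)` through the familial fitness map and take four times the
resulting variance (sire variance is a quarter of the additive variance in
a paternal half-sib design). Quadrature rather than `4 * var(b_hat)`
because shrunken point estimates systematically understate the variance;
in the lognormal single-node limit the quadrature matches the closed form
`e^{2s} - e^{s}` to 1e-6. We note the mapped quantity is an approximation:
the Gaussian-effects derivation of Va does not correspond exactly to any
functional of a non-Gaussian fitness distribution.

## The partition

All components use population (divisor-`n`) moments and equal family
weights — required for the weighted-mean and covariance forms of the Price
equation to agree exactly, and matching the convention that cohort mean
fitness is the plain average of familial fitnesses. `selection_change`
evaluates the same weighted-minus-unweighted expression as `total_change`
so that the total collapses to the selection component *bitwise* when
offspring and parental fitnesses coincide; round-off on constant input is
clamped to its exact zero. The residual is defined as the remainder, so
the four components sum to the total by construction.

Standard errors are delta-method forms through each cohort's full
within-cohort familial-fitness covariance (not just its diagonal), with
cross-cohort covariances set to zero — the two cohorts of a contrast are
separate field plantings analyzed independently. The residual's SE uses
the joint gradient of all three components per cohort block, not a naive
combination of component SEs; a Monte-Carlo check of this propagation is
in the test suite. Confidence intervals are normal-approximation
`estimate ± z * SE`.

The selection component involves one cohort's data; environmental and
total involve two. The selection SE is therefore systematically the
smallest — a pattern the recovery experiment reproduces in every
replicate.

## The synthetic-data generator

The generator emulates the field design the analysis assumes: G0 sires
each crossed to three dams, 30 seeds per full-sib family planted five to a
location at six randomized locations, transects of ~25 locations carrying
a shared environmental effect, pods thinned binomially into the counted
subsample, and a G2 generation grown from the realized seed output of the
year-1 G1 families with binomial subsampling at planting. Sire effects,
lineage-by-year interactions, and transect effects all enter the canonical
seed-node scale, matching the fitted model's geometry; G2 individuals
carry half the maternal-side sire effect through the (labeled) maternal
grandsire plus an independent per-individual pollen-pool draw of the full
sire variance, since G2 sires are unknown under open pollination.

Defaults, chosen once to sit inside the range the field system reports:
year-1 baselines `logit(0.30)` germination, `logit(0.50)` flowering,
`log(6)` pods, `log(3)` seeds per pod (cohort mean fitness ≈ 2.7 seeds per
seed planted); year 2 `logit(0.25)`, `logit(0.45)`, `log(4)`, `log(3)`
(≈ 1.35), giving a distinct-year environmental contrast of the size the
partition is meant to resolve; `sigma2_sire = 0.25`, `sigma2_gxe = 0.05`,
`block_sd = 0.2`, subsample rate 0.7, G2 planting fraction 0.25, 42 sires.
The generator's true familial fitnesses include the realized
lineage-by-year draws (they are what a cohort's fit estimates) and the
lognormal factors from block and pollen-pool heterogeneity.

What the generator does **not** emulate — and hence what passing recovery
tests cannot certify about real data: spatial autocorrelation along
transects, seed dormancy carrying over years, inbreeding depression in the
open-pollinated generation, unbalanced realized family sizes, and any
overdispersion beyond what block and pollen heterogeneity induce. Real
analyses should treat the recovery results as validating the estimator
under its own assumptions, not the assumptions themselves.

## Problem sizes and runtime choices

The test suite fits cohorts of 600–3,780 individuals; the end-to-end
recovery experiment uses 20 replicate two-generation experiments at the
full design (42 sires × 3 dams × 30 seeds), which completes in under two
minutes on one core because each mixed fit is a few hundred milliseconds.
The acceptance script uses one full experiment for the headline quantities
plus 10 replicates for the recovery fractions. Monte-Carlo tolerances are
stated in each test (3 Monte-Carlo SEs for mean checks; 2 SEs for
partition recovery with a ≥ 90% pass criterion over replicates).

## Known limitations

* Single random term per fit; no dam-plus-sire joint models, no
  multivariate aster models, no REML-style bias correction.
* The Laplace approximation's accuracy degrades for very small families or
  very low expected seed counts; the boundary diagnostics flag, but do not
  repair, separation in Bernoulli cells.
* SE propagation treats cohorts as independent; any shared machinery
  (common greenhouse effects, shared transects across years) would induce
  covariance the intervals ignore.
* The FTNS comparison is an approximation on two counts: familial effects
  stand in for additive genetic effects, and the variance mapping assumes
  the fitted Gaussian-on-canonical-scale model.
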