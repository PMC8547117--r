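---
title: "Measuring premature mortality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring premature mortality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premort)
```

## The measurement problem

"Premature mortality" is a latent concept: deaths that occurred too
early. Operational definitions fall into two families. *Absolute*
measures fix an age threshold (65, 70, 75) or a standard life
expectancy and count, rate or weight the deaths below it. They are easy
to compute and interpret, but the threshold is arbitrary, and two
populations can swap ranks when the threshold moves. *Relative*
measures instead decompose the life-table age-at-death distribution
$d(x)$ into overlapping curves — a premature curve hiding under the
old-age ("senescent") curve — so each population carries its own
implicit threshold. Their weakness is the mirror image: the premature
share depends on where the population's own senescent curve sits, so a
high-longevity population with a compressed, right-shifted senescent
curve can be assigned *more* premature mortality than a lower-longevity
one, which confounds cross-country comparison.

`premort` implements both families and, as its core, a *hierarchical*
compromise: a group of comparable populations is assumed to share one
senescent curve, while each population keeps its own premature curve
and mixture weight. Within a group, every death at a given age is then
judged against the same benchmark, and the mixture weights are directly
comparable.

## Models

All distributional components are skew-normal. In the direct
parametrization (DP), the density with location $\xi$, scale $\omega$
and shape $\lambda$ is

$$f(x) = \frac{2}{\omega}\,\phi\!\Big(\frac{x-\xi}{\omega}\Big)\,
  \Phi\!\Big(\lambda\,\frac{x-\xi}{\omega}\Big).$$

Estimation and priors use the centered parametrization (CP)
$(\mu, \sigma, \gamma)$ — mean, standard deviation, skewness — which is
interpretable and better behaved near symmetry. The two are linked by
the closed-form transform implemented in `cp_to_dp()` / `dp_to_cp()`;
the skewness of this family is bounded,
$|\gamma| < 0.9953$ (`max_abs_skewness()`), which is why all skewness
priors below are truncated to $\pm 0.995$.

**Relative model** (per population, `fit_relative()`): the death
density is

$$d(x) = \eta f_I(x) + (1-\eta)\,\alpha\, f_m(x) +
  (1-\eta)(1-\alpha)\, f_M(x),$$

with $f_I$ an infant/child component, $f_m$ the premature and $f_M$ the
senescent skew-normal, and $\alpha$ the premature share among
non-infant deaths. When the density starts at age 5 (the default
analysis support), $\eta$ is fixed at 0.

**Hierarchical model** (per group, `fit_hierarchical()`): for
population $j$ on ages 5–110,

$$d_j(x) = \alpha_j\, f^m_j(x;\mu^m_j, \sigma^m_j, \gamma^m_j)
  + (1-\alpha_j)\, f^M(x;\mu^M, \sigma^M, \gamma^M),$$

with priors

$$\alpha_j \sim U(0, 0.9),\quad
  \mu^m_j \sim N(60, \sigma^2_{\mu^m})\,T[-\infty, 75],\quad
  \sigma^m_j \sim U(0, 20),$$
$$\gamma^m_j \sim N(0, \sigma^2_{\gamma^m})\,T[-0.8, 0.995],\quad
  \mu^M \sim N(87, 4),\quad \sigma^M \sim U(0, 9),$$
$$\gamma^M \sim SN(-1, 0.5, 1)\,T[-0.995, 0.995],\quad
  \sigma_{\mu^m} \sim U(0, 2.5),\quad
  \sigma_{\gamma^m} \sim U(0, 0.2).$$

The truncations are doing real work: keeping $\mu^m_j \le 75$ while
$\mu^M$ is anchored near 87 prevents the two components from swapping
roles (label switching), so no post-hoc relabeling is needed.

## Decisions the model statement leaves open

Several details are not pinned down by the model statement above; the
package resolves them as follows, each exposed as an argument so the
choice can be revisited.

* **Observation model.** The likelihood is multinomial over single-year
  age bins: model cell probabilities are CDF differences of the mixture
  over $[a, a+1)$, renormalized on the grid, and each population
  contributes `effective_n` pseudo-deaths (defaulting to its life-table
  death count above age 5). This respects the compositional nature of
  $d(x)$ and makes posterior width shrink with data size. CDF
  differences, not midpoint density values, are used so that mass is
  preserved exactly on the coarse grid.
* **$N(87, 4)$ for $\mu^M$** is read as variance 4 (sd 2); the reading
  is a `prior_spec(mu_M_sd = )` knob since the notation is ambiguous.
* **$SN(-1, 0.5, 1)$ for $\gamma^M$** is read in the direct
  parametrization.
* **Hyper-centers** (60 for $\mu^m_j$, 0 for $\gamma^m_j$) are fixed
  constants, not hyper-sampled.
* **The infant component.** The printed kernel
  $(\sqrt{2}/\pi)\exp(-x^2)$ is not a unit-mass density and carries no
  age scale. The default is therefore the unit-mass half-normal
  $\sqrt{2/\pi}\,e^{-x^2/2s^2}/s$ with scale $s$ in years
  (`infant_density()`, default $s = 1$); the literal printed form stays
  available behind `form = "printed"` for comparison.
* **Pooling.** `pool_group()` averages member densities with equal
  country weights: life tables are already standardized, and the pooled
  "super-country" is meant as a reference shape, not a
  population-weighted aggregate.
* **Open age interval.** Deaths at 110+ sit on the single terminal age;
  the model density is renormalized on the grid, and senescent mass
  beyond 110 is negligible for the parameter ranges involved.

## Sampling and diagnostics

The posterior is sampled with component-wise adaptive random-walk
Metropolis on unconstrained scales (logit-type transforms for bounded
parameters, $75 - e^z$ for the upper-truncated premature means, with
Jacobian corrections). Two features matter for mixing:

* per-parameter proposal scales adapt toward 44% acceptance during
  warmup (Robbins–Monro, frozen at the end of warmup);
* from mid-warmup on, joint block proposals are added — one 4-d block
  per population $(\alpha_j, \mu^m_j, \sigma^m_j, \gamma^m_j)$ and one
  3-d block for the shared senescent triple — with proposal covariance
  estimated from the warmup draws and a scalar step factor adapted
  toward 25% acceptance. These blocks move the sampler along the
  correlated ridges (e.g. $\mu^M$–$\sigma^M$, $\alpha_j$–$\mu^m_j$)
  where univariate updates diffuse slowly.

Per-population likelihood terms are cached, so an update of one
population's parameters re-evaluates only that population's cells.
Chains start from moment-based values (pooled modal age at death,
premature mean 20 years below it, $\alpha_j$ from the mass below the
mode) plus chain-specific jitter; every random draw derives from
`mcmc_config(seed = )`, so fits are exactly reproducible.

Convergence is summarized by split R-hat (`compute_rhat()`): each chain
is halved and $\hat R = \sqrt{\hat{v}^+/W}$ compares between- and
within-half variances. A fit with any $\alpha_j$ R-hat above 1.1 is
returned but flagged `converged = FALSE`. Degenerate constant chains
report 1 with a `degenerate` attribute. Defaults are 4 chains with
1000 warmup + 1000 kept iterations; the validation experiments below
use up to 1500 + 1500, which brings all R-hat below 1.05 for
$10^5$-death groups.

Group membership is itself a modeling decision, and a wrong one shows
up as misfit: `assess_group_fit()` reports, per population, the
total-variation distance between the posterior-mean model density and
the data (flagged above 0.05 by default) plus a posterior-predictive
p-value from multinomial replicates. The shared senescent curve is
estimated jointly on the group by default; passing `senescent =` holds
it fixed at a designated benchmark (e.g. a reference country's curve
estimated with `fit_relative()`).

Numerical notes: the skew-normal CDF is evaluated via Owen's T function
(48-point Gauss–Legendre after reduction to $|a| \le 1$, accurate to
near machine precision); cell masses are clamped at 0 against
floating-point jitter in the far tails; the CP skewness bound is
enforced as an open interval with $10^{-6}$ headroom at the truncation
points; in `fit_relative()` the premature mean is bounded into
$[\max(\text{min age}, 15), 75]$ because letting it drift off-grid
would zero the component's grid mass and leave $\alpha$ unidentified
(the hierarchical prior's $N(60, \sigma_{\mu^m})$ shrinkage rules this
out by itself).

## What the synthetic generator does and does not emulate

All validation runs on synthetic data from `synthetic_scenario()` /
`simulate_group()`: exact mixture cell probabilities on ages 5–110,
optionally replaced by one multinomial draw of $n$ deaths (matching the
likelihood's observation model), written to HMD-layout files where
file I/O is involved. Scenario defaults are chosen to mimic national
life tables: $10^5$ deaths (a life-table radix), senescent means 87
(high-longevity) or 80 (medium), sd 6–7, slight left skew; premature
means 54–62 with sd 10–12; $\alpha$ between 0.05 and 0.40.

This emulates the generative structure the model assumes, which is
exactly what parameter-recovery tests require — and no more. Real
life-table densities are not finite mixtures of two skew-normals: they
carry age heaping, cohort artifacts, smoothing from the life-table
construction itself, and premature components that need not be
unimodal. Passing recovery tests therefore demonstrates correctness of
the fitting machinery, not adequacy of the mixture for any particular
country. The group-dependence experiment (the same synthetic country
placed in a high- vs medium-longevity group yields a strictly larger
premature share in the former) reproduces the mechanism by which group
assignment drives the estimate — the package's analogue of Chile's
published behavior — qualitatively, not numerically, since the real
Latin American life tables cannot be shipped.

Problem sizes used by the validation suite: recovery uses one
4-population group at $n = 10^5$ deaths each with 4 chains of
1500 + 1500 iterations; the coverage experiment uses ten 3-population
groups with 2 chains of 800 + 800; smoke tests use $n \le 2\times10^4$
with a few hundred iterations.

## Worked example

```{r example, fig.width = 7, fig.height = 5, eval = FALSE}
scenario <- preset_scenarios()[["high_longevity"]]
gd <- simulate_group(scenario)
fit <- fit_hierarchical(gd, mcmc = mcmc_config(seed = 1))
premature_prevalence(fit)
assess_group_fit(fit)
plot(fit)

# absolute measures on a synthetic life table
tab <- synthetic_lifetable(sn_cp(80, 10, -0.4),
                           premature = sn_cp(55, 10, 0.3), alpha = 0.25)
absolute_measures(tab)

# relative fit of a single population
rel <- fit_relative(gd$densities[[4]])
coef(rel)
```

## Known limitations

* Groups are taken as given; choosing them is a substantive decision
  the package only audits post hoc (via `assess_group_fit()`), it does
  not cluster countries automatically.
* Years are fitted independently; there is no smoothing of $\alpha_j$
  over time.
* Only single-year (1x1) period life tables are supported — no
  abridged or cohort tables, and no download client for the mortality
  databases.
* The multinomial `effective_n` is a pseudo-count: life-table deaths
  are synthetic-cohort constructs, so posterior intervals quantify
  sampling variation under that convention rather than true
  population-level uncertainty.
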