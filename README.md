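# premort

Premature mortality measured from period life tables, three ways.

Deaths that occur "too early" can be counted against a fixed age
threshold (the *absolute* view: rates below 65/70/75, potential years
of life lost), or read off the population's own age-at-death
distribution d(x) as a mixture component hiding under the old-age curve
(the *relative* view). Both break down in cross-country comparison: the
threshold is arbitrary and can reverse rankings, while the relative
share depends on where each country's own senescent curve happens to
sit. `premort`'s core is a *hierarchical* Bayesian compromise for a
group of comparable populations, fitted on ages 5–110:

    d_j(x) = alpha_j * f_m(x; mu_m_j, sigma_m_j, gamma_m_j)
             + (1 - alpha_j) * f_M(x; mu_M, sigma_M, gamma_M)

where f_m and f_M are skew-normal densities in centered
parametrization (mean, sd, skewness; |skewness| < 0.995). The
senescent component f_M is shared by the whole group, each population
keeps its own premature component and weight `alpha_j`, and weakly
informative truncated priors (premature mean at most 75, senescent mean
centered at 87) keep the two components from trading places. The
posterior is sampled with an adaptive Metropolis scheme (univariate
scans plus covariance-learned block proposals), with split R-hat
diagnostics; `alpha_j` is the premature-mortality prevalence of
population j, comparable within the group because every population is
judged against the same senescent benchmark.

The package is intended for demographers and health-systems
researchers comparing premature mortality across countries, regions or
sexes from Human Mortality Database-style 1x1 period life tables.

## Worked example

```r
library(premort)

# a group of four synthetic populations sharing a senescent curve
# (mean 87, sd 6, skewness -0.5) with known premature weights
scenario <- preset_scenarios()[["high_longevity"]]
gd <- simulate_group(scenario)
fit <- fit_hierarchical(gd, mcmc = mcmc_config(seed = 11))
premature_prevalence(fit)
#>   population      alpha      lower      upper     rhat rank
#> 1       HL-A 0.04799727 0.04535098 0.05113106 1.044363    1
#> 2       HL-B 0.11768477 0.11384047 0.12181177 1.023693    2
#> 3       HL-C 0.20069242 0.19460405 0.20691892 1.021688    3
#> 4       HL-D 0.29677426 0.29170836 0.30209725 1.015058    4
```

The generating weights were 0.05, 0.12, 0.20 and 0.30: each posterior
mean lands within half a point of its truth, the 95% credible
intervals are a few tenths of a point wide (10^5 deaths per
population), all R-hat values are near 1, and the within-group ranking
(1 = least premature mortality) is recovered exactly.

Absolute measures and the single-population relative fit share the same
life-table objects:

```r
tab <- synthetic_lifetable(sn_cp(80, 10, -0.4),
                           premature = sn_cp(55, 10, 0.3), alpha = 0.25)
absolute_measures(tab)
#>   population year      m_band    pyll frac_below_65 frac_below_70 frac_below_75
#> 1        SYN 2010 0.008370755 1340697       0.26805       0.34936       0.45881

rel <- fit_relative(to_death_density(tab))
round(coef(rel), 3)
#>     eta   alpha    mu_m sigma_m gamma_m    mu_M sigma_M gamma_M
#>   0.000   0.253  55.171  10.111   0.317  80.055   9.963  -0.396
```

Real HMD files are read with `read_hmd_lifetable(path, year)`; a thin
command line over the same functions lives in `inst/cli/premort.R`
(subcommands `simulate`, `fit-relative`, `fit-hierarchical`,
`measures`; see `?premort_cli`).

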