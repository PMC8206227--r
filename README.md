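# fishdemog

Bayesian demographic analysis of coral-reef fish under seabird nutrient
subsidies.

Invasive rats wipe out island seabird colonies and with them the flow of
pelagic nutrients (guano) onto adjacent reefs. `fishdemog` is for reef-fish
ecologists and fisheries scientists who want to compare demographic rates of
a focal species — here, a parrotfish — between **rat-free** (seabird-rich)
and **rat-infested** (seabird-poor) islands, from three standard data
streams: aged/staged fish collections, belt-transect visual surveys, and
island covariates.

At its core is a von Bertalanffy growth model with a treatment offset on the
growth coefficient,

```
L_t = L∞ − (L∞ − L0) · exp(−(k + k_b · ratfree) · t),
```

so that `k_b` is directly the growth-rate difference between island types.
Around it the package implements, as one coherent tidyverse-style toolkit:

* growth-model variants (offset on `k`, offset on `k` and `L∞`, no offset)
  with PSIS-LOO model comparison, a three-age (Francis) reparameterization,
  and per-draw derived contrasts (percent faster growth, length-at-age
  differences, upper-quartile maximum age/length);
* gonadosomatic-index (GSI) regressions for reproductive investment and an
  individual-level growth-fecundity correlation;
* hurdle-gamma models for zero-inflated transect density/biomass and an
  exponentially modified Gaussian (ex-Gaussian) size-structure model with
  treatment effects on mean and skew;
* driver models (seabird density ratios, tissue %N, δ15N);
* propagation of growth posteriors into allometric grazing/bioerosion rates
  and a population-level reproductive-potential proxy;
* a synthetic-data generator with the exact generative structure the models
  assume, so every estimator is validated by simulation-based parameter
  recovery without the field data.

Fitted objects are tibble-first: `tidy()`, `glance()`, `autoplot()` work on
every model, and all MCMC (JAGS via rjags; 4 chains × 3000 iterations,
1000 warmup by default) is exactly reproducible under a single seed, with
rank-normalized split R-hat, effective sample sizes, HPDI summaries, and
posterior predictive checks built in.

## Worked example

Simulate a study at the default (study-like) conditions — 8 islands in 3
atolls, 15 fish per island, growth offset `k_b = 0.10` — and fit the primary
growth model:

```r
library(fishdemog)

study <- simulate_study(synthetic_config(seed = 2025))
fit <- fit_vbgf(study$fish, variant = "offset_k",
                mcmc = mcmc_config(seed = 2025))
tidy(fit)
#>   term  estimate conf.low conf.high hpdi75_low hpdi75_high  rhat   ess
#> 1 L_0      8.37    7.00       9.59      7.65         9.16   1.02  291.
#> 2 L_inf   25.0    24.1       26.0      24.5         25.6    1.02  282.
#> 3 k        0.266   0.221      0.316     0.236        0.293  1.03  186.
#> 4 k_b      0.102   0.0669     0.139     0.0803       0.123  1.01  606.
#> 5 sigma    1.10    0.971      1.26      1.02         1.19   1.00 4368.
```

The posterior of `k` (rat-infested growth coefficient) sits on the
generating 0.27 and the offset `k_b` on the generating 0.10, with the 95%
HPDI (`conf.low`/`conf.high`) excluding zero — growth is credibly faster
around rat-free islands. Derived contrasts propagate the joint posterior:

```r
percent_growth_difference(fit)
#>   quantity                  median hpdi95_low hpdi95_high
#> 1 percent_growth_difference   38.3       27.7        50.1

length_at_age_contrast(fit, ages = c(2, 4, 6))
#>     age median hpdi95_low hpdi95_high
#> 1     2   1.80       1.30        2.34
#> 2     4   1.92       1.47        2.42
#> 3     6   1.53       1.15        1.94
```

i.e. a ~38% faster growth coefficient, and fish ~1.9 cm longer at age 4
around rat-free islands. Reproductive investment runs the other way:

```r
gsi <- fit_gsi_model(study$fish, covariate = "length",
                     mcmc = mcmc_config(seed = 2025))
gsi$gsi
#>   quantity               median hpdi95_low hpdi95_high
#> 1 gsi_rat_infested        1.17       0.893       1.46
#> 2 gsi_rat_free            0.809      0.508       1.07
#> 3 difference             -0.365     -0.574      -0.161
#> 4 percent_lower_rat_free 31.0       14.6        48.0
```

Length-adjusted GSI is credibly lower around rat-free islands (this seed
drew a stronger-than-average contrast; the generating shift is −0.25) — the
growth-reproduction trade-off the package is built to quantify.
`autoplot(fit)` draws the fitted growth curves over the data;
`run_pipeline(pipeline_config(...))` runs every suite end to end and writes
consolidated CSV/JSON reports.

Real data enter through `read_fish_table()`, `read_transect_table()`,
`read_island_table()` and `read_length_weight()` (CSV schemas documented on
those help pages, with column-name mapping). Allometric grazing/bioerosion
coefficients are user-supplied by design — see `allometric_coefficients()`.

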