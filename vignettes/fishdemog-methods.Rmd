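---
title: "Models and methods: reef-fish demography under seabird nutrient subsidies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: reef-fish demography under seabird nutrient subsidies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Invasive rats suppress island seabird colonies, cutting off the flow of
pelagic-derived nutrients (guano nitrogen and phosphorus) to nearshore coral
reefs. `fishdemog` implements a Bayesian workflow for asking what that loss
does to the demography of a reef fish: do individuals around rat-free,
seabird-rich islands grow faster, invest differently in reproduction, and
reach larger sizes than conspecifics around rat-infested islands, and do
those individual-level differences propagate to population structure and to
size-dependent ecosystem functions (grazing, bioerosion)?

The design the package targets is a paired-island comparison: islands nested
in atolls, each island either `rat_free` or `rat_infested`, with three data
streams:

* a **collection table** — one aged (otolith-read), measured, staged fish per
  row, with gonad mass for females and muscle %N / delta-15N;
* a **survey table** — underwater visual-census belt transects (30 m x 5 m,
  150 m^2, fish > 8 cm recorded to the nearest cm), including true zero
  transects;
* an **island covariate table** — breeding-seabird density, SST, wave
  exposure, net primary productivity, island area.

# Growth: von Bertalanffy with a treatment offset

Length-at-age is modelled as Gaussian around the von Bertalanffy growth
function (VBGF)

$$L_t = L_\infty - (L_\infty - L_0)\,e^{-(k + k_b\,\mathrm{ratfree})\,t},$$

where $L_\infty$ (cm) is the asymptotic length, $L_0$ (cm) the theoretical
length at age 0, and $k$ (yr$^{-1}$) the growth coefficient. The single
offset $k_b$ is the effect of interest: both treatments share $L_\infty$ and
$L_0$, so $k_b > 0$ means fish around rat-free islands approach the same
asymptote faster. Two alternative variants support model criticism: one that
also offsets $L_\infty$, and a null with no offset at all; `compare_models()`
ranks them by PSIS-LOO expected log predictive density.

Assumptions worth stating: residuals are homoscedastic in length-at-age
(the mean function is the only structural treatment difference); ages are
known integers $\ge 1$; no atoll term appears in the growth mean by default,
because the growth model is fit to the pooled collection — a configuration
switch (`atoll_on_L0`) adds an atoll varying intercept on $L_0$ for users
who want island-group structure in growth as well.

**Priors** (all overridable): $L_\infty \sim N(1.1\,L_{max}, (0.3\,L_{max})^2)$
truncated below at $L_0$; $L_0 \sim N(8, 5^2)$ truncated at 0;
$k \sim N^+(0, 0.5^2)$; $k_b \sim N(0, 0.25^2)$;
$\sigma_L \sim N^+(0, 5^2)$. We deliberately truncate $L_\infty$ at $L_0$
rather than at the largest observed fish: with realistic residual noise
($\sigma_L \approx 1$ cm) individual fish routinely exceed the population
asymptote, and conditioning $L_\infty$ to lie above the sample maximum
biases it upward and drags the posterior of $k_b$ off the generating value
in simulation. Truncation at $L_0$ keeps the curve well-defined without
constraining the asymptote by an order statistic of the noise.

Derived quantities are computed per posterior draw, never from point
estimates: the percent growth difference is the median of
$100\,k_b/k$ across draws (propagating the joint uncertainty — a ratio of
medians would not), and length-at-age contrasts are per-draw differences of
the two mean curves at requested ages.

## Three-age (Francis) reparameterization

The same likelihood can be parameterized by the mean lengths
$\ell_\phi < \ell_\chi < \ell_\psi$ at three equally spaced reference ages
(default 2, 4, 6 yr, the range with data support in both treatments), with

$$r = \frac{\ell_\psi - \ell_\chi}{\ell_\chi - \ell_\phi}, \qquad
L(t) = \ell_\phi + (\ell_\psi - \ell_\phi)
\frac{1 - r^{2(t - \tau_\phi)/(\tau_\psi - \tau_\phi)}}{1 - r^2}.$$

This puts the parameters on the scale of the data (lengths at observed
ages), which makes priors easy and the treatment contrast at intermediate
ages direct. The closed-form inverse
($k = -2\log r/(\tau_\psi - \tau_\phi)$,
$L_\infty = \ell_\phi + (\ell_\psi - \ell_\phi)/(1 - r^2)$) is verified by a
round-trip property test at $10^{-9}$ and by checking that maximum-likelihood
fits in the two parameterizations produce the same fitted curve to
$10^{-6}$ cm; the published source of the mapping is not reproduced here, so
the algebra is validated by these properties rather than by citation. Each
treatment gets its own $(\ell_\phi, \ell_\chi, \ell_\psi)$ with a shared
residual SD; the ordering constraint is imposed by truncated priors.

## Upper-quartile extremes

Longevity and maximum size are compared through a robust proxy: per island,
the mean of the observations at or above the island's 75th percentile
(linear-interpolation quantile, inclusion rule $\ge$), then a Gaussian
island-level model with treatment effect and atoll varying intercept.
Islands with fewer than 4 fish fall back to their full-sample mean and are
flagged. Because collections are initial-phase females of a protogynous
species, these contrasts proxy age- and size-at-sex-change rather than
absolute maxima.

# Reproductive investment: GSI

The gonadosomatic index is GSI $= 100 \times$ gonad mass / body mass, with
body mass converted from kg (as weighed) to g inside the ratio. Only
spawning-capable females carry information about investment, so the GSI
model is restricted to them. The default model is Gaussian on the raw
percent scale — matching the additive way differences are reported — with
treatment, a centered length covariate, and an atoll varying intercept;
variants swap length for age or add collection day. Centering means the
treatment coefficient is the difference at the sample-mean covariate; the
percent difference is computed per draw relative to the rat-infested
adjusted level.

The individual growth-fecundity trade-off is estimated from model deviates:
each female's growth deviate is her observed length minus the per-fish
posterior median of the VBGF mean at her age and treatment; her GSI deviate
is observed GSI minus the per-fish posterior median fitted GSI at her length
and treatment. The Pearson correlation of the deviates, with a 2000-resample
nonparametric bootstrap interval, is a declared stand-in construction: it
has the right null behaviour (property-tested) but mildly attenuates strong
latent correlations, because the fitted GSI-on-length slope absorbs part of
any correlated variance.

# Population structure

Transect **density and biomass** are semicontinuous (many true-zero
transects), so both use a hurdle-gamma family: a logit-scale probability of
a structural zero (intercept-only by default, optionally with a treatment
term) and a log-link gamma mean for the positive part with treatment effect
and atoll intercept. Log-link treatment effects back-transform per draw to
ratios (`back_transform_ratio()`), reported as rat-free : rat-infested.

**Size structure** uses an exponentially modified Gaussian (ex-Gaussian):
length $= \mu + \mathrm{Normal}(0, \sigma) + \mathrm{Exp}(\tau)$, where the
exponential component $\tau$ (cm) governs the right skew — the "skew
parameter" of the analysis. Treatment enters $\mu$ additively and $\tau$ on
the log scale; the derived mean is $\mu + \tau$ per draw, so mean-size and
skew contrasts come from one model. The likelihood is fitted by exact data
augmentation (a latent exponential per fish), which is numerically robust;
the closed-form ex-Gaussian density is used for pointwise log-likelihood.
Surveyed lengths are pooled per fish across transects by default (transect
identity is not modelled); an atoll intercept on $\mu$ is available. The
survey's 8 cm cutoff is respected by the generator but the fitted
distribution is untruncated, as is conventional; with the default size
scale the mass below 8 cm is negligible.

# Drivers

Strictly positive island covariates (seabird density) use the lognormal
family, so the treatment effect is a multiplicative ratio; zeros, if
present, are offset by half the smallest positive value with a prominent
log message. Tissue %N and delta-15N are Gaussian with atoll intercepts.

# Inference machinery

All models run on JAGS through `rjags` — an established Gibbs/Metropolis
engine — under a common contract: 4 chains, 3000 iterations, 1000 warmup by
default (`mcmc_config()`), per-chain RNG seeds derived from one integer so
every fit is exactly reproducible. Around the sampler the package provides:

* **HPDI** — the narrowest contiguous window containing
  $\lceil \text{mass} \cdot n \rceil$ sorted draws, ties broken toward the
  smallest lower bound; property-tested against a brute-force window scan.
* **R-hat** — rank-normalized split R-hat (max of bulk and folded); fits
  warn above 1.01. Zero-variance chains report NA with a warning.
  Divergence counts are reported as NA: they are a Hamiltonian-sampler
  diagnostic with no Gibbs analogue.
* **Model comparison** — PSIS-LOO implemented in the package (generalized
  Pareto tail fit by the Zhang-Stephens profile likelihood, with the usual
  regularization toward $k = 0.5$), with pairwise SEs of pointwise
  differences.
* **Posterior predictive checks** — observed mean/SD/min/max (and zero
  fraction where meaningful) located among >= 200 replicate datasets.

Default priors for the regression-style models are weakly informative and
scale-aware: coefficients $N(0, 2.5\,\mathrm{sd}(y)/\mathrm{sd}(x))$,
intercepts $t_3(\mathrm{median}(y), 2.5\,\mathrm{mad}(y))$, SD-like
parameters half-$t_3(0, 2.5\,\mathrm{mad}(y))$, all overridable.

Degenerate inputs are handled explicitly rather than sampled: a constant
response has an unbounded likelihood as $\sigma \to 0$, so the fit returns
the exact limit (point mass, zero effect) with a warning; empty data errors
unless `prior_only = TRUE` is requested.

# The synthetic-data generator

`synthetic_config()` fixes a complete generative model whose defaults are
the study conditions: 3 atolls with 2+1+1 paired islands per treatment
(8 islands), 15 fish per island, ages uniform on 1-8 yr (the catch's age
distribution is unreported, so uniform is the configurable stand-in),
growth at $(L_\infty, L_0, k, k_b, \sigma_L) = (25, 8, 0.27, 0.10, 1)$,
GSI intercept 1.20% with treatment shift $-0.25$ and residual SD 0.45
(anchored to the reported interval widths), latent growth-GSI correlation
$-0.26$ injected at the bivariate-standard-normal deviate level, per-transect
occupancy 14/24 and 8/20, gamma-distributed positive counts (mean 8 vs 5.6,
shape 1.5), ex-Gaussian sizes with means 14.3 vs 16.6 cm and $\tau$ 1.8 vs
2.26 cm, and a 760-fold lognormal seabird-density ratio. The GSI length
slope is deliberately weak (0.02 %/cm) so that length-, age-, and
day-adjusted GSI models estimate nearly identical treatment differences, as
the study system exhibits. Wet weight follows a synthetic length-weight
power law (a = 0.0125 g cm$^{-3}$, b = 3) with 5% lognormal noise — these
coefficients are labelled synthetic and are not the published values, which
must be supplied by the user for real analyses.

Reproductive stages are drawn with spawning-capable females dominant
(~85%), so a default run yields ~100 females, matching the study-like n.
Lengths are recorded to 0.1 cm (collections) or the nearest cm (surveys) to
mirror measurement precision; simulated counts are rounded with a floor of
one fish on occupied transects, keeping the hurdle exact.

What the generator does *not* emulate — and what passing recovery tests
therefore cannot certify about real data: spatial structure within reefs,
transect-level autocorrelation, size-selective catchability, sex change
dynamics, seasonal growth, ageing error, or model misspecification (the
fitted families are the generating families). Recovery tests certify the
estimators, not the biology.

# Numerical choices

* RNG: each generator block (ages, growth deviates, GSI deviates, weights,
  isotopes, stages, transects, islands) draws from its own seed-offset
  stream, so changing one parameter block perturbs only its own columns.
* GSI values implied below zero by the linear model are floored at 0 (gonad
  mass is physical); the count of floored rows is messaged.
* The ex-Gaussian $\tau = 0$ limit degenerates cleanly to the normal in
  both the generator and the density.
* HPDI tie-break and the upper-quartile inclusion rule are fixed as stated
  so results are bit-reproducible.
* Allometric functional rates ship with *no* default coefficients: grazing
  and bioerosion scalings are published externally and fabricating defaults
  would invite silent misuse. `propagate_function()` maps the per-draw
  length-at-age through $c\,L^d$; the reproductive-potential proxy (predicted
  gonad mass from the GSI model summed over surveyed fish per transect) is a
  documented conservative construction whose assumptions are attached to its
  output.

# Problem sizes

The shipped tests run the full recovery harnesses at the study's own scale:
20 replicates of 8 islands x 15 fish for growth and GSI recovery (2 chains
x 1500 iterations per fit), 200 transects for the hurdle check, and 20
replicates of 500 lengths per treatment for the skew contrast. The
`scripts/acceptance.R` run uses the default 4 x 3000 sampler settings on one
simulated study. These sizes were chosen to match the design the models are
meant for; at them, the complete suite runs in a couple of minutes on a
single core.

# Known limitations

* The growth-fecundity correlation estimator attenuates strong latent
  correlations slightly (see above); at n ~= 96 females its sampling SE is
  ~0.1, so individual estimates scatter widely around the truth.
* Hurdle and size-structure models ignore transect identity; per-fish
  pooling is the default and transect-level grouping is out of scope.
* PSIS-LOO diagnostics (`max_khat`) should be checked before trusting a
  ranking; heavy tails are reported, not auto-corrected.
* The package analyses one species at a time; survey tables may contain
  other species but filters and coefficients are per-species inputs.
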