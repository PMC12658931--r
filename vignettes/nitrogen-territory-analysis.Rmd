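---
title: "Modelling nitrogen-deposition effects on breeding-bird territory numbers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nitrogen-deposition effects on breeding-bird territory numbers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`birdNdep` estimates how breeding-bird territory numbers relate to
atmospheric nitrogen (N) deposition across a gridded 1-km survey design,
and aggregates species-level results into ecological-guild summaries. This
vignette is the package's methodological account: the model, the slope
extraction, the synthetic data the pipeline is tested on, and the numerical
decisions behind both.

## The territory model

The response is the number of territories of one species in one survey
area and year — a non-negative count with many zeros and strong
overdispersion. Counts are modelled with a zero-inflated negative binomial
(ZINB): with probability $\pi_0$ an observation is a structural zero;
otherwise it is negative binomial with mean $\mu$ and dispersion $\phi$,

$$\Pr(y = k) = \pi_0\,\mathbf{1}\{k = 0\} + (1 - \pi_0)\,
\mathrm{NB}(k \mid \mu, \phi), \qquad
\mathrm{Var}(y \mid \text{count process}) = \mu + \mu^2/\phi.$$

The mean-dispersion parameterization is fixed package-wide — the simulator
draws from it and the likelihood evaluates it — so the generative model and
the fitted model cannot silently disagree. The linear predictor is

$$\log \mu = \alpha + x_N\beta_1 + x_N^2\beta_2 + x_N^3\beta_3 +
\mathbf{x}'\boldsymbol\gamma + u_{\text{year}},$$

where $x_N$ is standardized log N and the cubic allows the dose-response
to bend and saturate. Habitat covariates $\mathbf{x}$ follow field
conventions: elevation, forest, arable and road fractions enter linear
plus quadratic; settlement enters linearly; rocks, wetland and shoreline
amounts are mostly zero and are reduced to presence/absence; grassland is
omitted because the cover fractions are near-redundant (they sum to
roughly one); arable terms are dropped for alpine species, which breed
where arable land barely exists. All continuous covariates are centred and
scaled to 1 SD over the species' included areas; the quadratic and cubic
columns are raw powers of the standardized value, which keeps the cubic's
coefficients directly usable by the analytic shape classifier. Year enters
as a random intercept $u_{\text{year}} \sim N(0, \sigma_y^2)$, drawn once
per species and year.

The species' N variable is atmospheric deposition in kg N/ha/yr; for
farmland species it is deposition plus agricultural N application, because
applied manure and fertilizer dominate the N input on farmland. The two
quantities are summed as reported, without rescaling.

Zero inflation is intercept-only: no covariates are proposed for $\pi_0$,
matching the default of the common ZINB fitting frameworks and keeping the
mixture identifiable at modest sample sizes.

### Priors and inference

Inference is Bayesian with weakly informative priors on the unconstrained
scale: Normal(0, 2.5) on standardized coefficients, Student-t(3, 0, 2.5)
on the intercept, Logistic(0, 1) on $\mathrm{logit}\,\pi_0$ (uniform on
the probability), Exponential(1) on $\phi$ and half-Normal(0, 1) on
$\sigma_y$, each with the appropriate log-scale Jacobian. Year effects use
the non-centred parameterization ($u = \sigma_y z$, $z \sim N(0,1)$), the
standard remedy for funnel geometry with few year levels.

Two back ends share one contract ([fit_zinb()]):

* **`map_laplace`** (default): BFGS finds the posterior mode of the
  unconstrained parameter vector; draws come from the Gaussian
  approximation at the mode (covariance from the numerical Hessian, with a
  ridge fallback if it is not positive definite). Deterministic given the
  seed, and fast enough that hundreds of species-level fits run in
  minutes.
* **`mcmc`**: adaptive random-walk Metropolis started at the mode, with
  the Laplace covariance (scaled by $2.38^2/p$) as proposal shape.
  Convergence is summarized by split-chain scale reduction; values above
  1.05 are flagged in the fit's metadata, never silently dropped.

The two back ends agree on posterior means to a fraction of a posterior SD
on well-identified data (tested). The Gaussian approximation has one
known failure mode, covered by a test: when every count is zero, only the
mixture's total zero probability is identified and the posterior is a
ridge in $(\pi_0, \mu)$; posterior-predictive checks of such degenerate
fits use the MCMC back end.

Model criticism follows standard practice: posterior predictive checks on
the zero fraction, mean, maximum and variance (p-values use the midpoint
rule for ties, necessary for discrete statistics such as the zero
fraction), randomized-quantile residuals with the ZINB cdf averaged over
draws, and an empirical semivariogram of per-area mean residuals as a
screen for residual spatial autocorrelation.

## From posterior draws to linear relationships

A cubic on the log scale makes raw coefficients incomparable across
species, so effect sizes are extracted geometrically:

1. **Elevation bands.** Included areas are partitioned into six elevation
   bands (default inner edges 600, 1000, 1400, 1800, 2200 m, configurable;
   intervals closed on the left, last closed on the right). Bands with
   fewer than 5 areas — or without any spread in observed N — are dropped,
   and the species' territory shares over the retained bands are
   renormalized to sum to 1. Separating bands matters because N and
   elevation are strongly anticorrelated; a single pooled curve would
   confound the two.
2. **Effect curves.** Per posterior draw, expected territories
   $(1-\pi_0)\exp(\alpha + x'\beta)$ are evaluated along N within the
   band's *observed* N range, with non-N covariates at their
   species-specific means (presence covariates at their most frequent
   level, following the convention of setting factors to the mode), the
   elevation terms at the band's median member elevation, and the year
   effect at zero. The zero-inflation factor is included because the
   quantity of interest is the expected breeding-pair count, not the
   count-process mean; this choice is recorded in the output metadata.
3. **Percentile secants.** Per draw and band, the slope of the straight
   line through the curve at the 15th and 85th percentiles of observed N
   in that band (evaluated exactly, not interpolated from a grid), scaled
   per 10 kg N/ha/yr — 40 kg for farmland species, whose summed N variable
   spans roughly four times the range. Percentiles are taken on the raw
   N axis, because slopes are reported per kg N.
4. **Aggregation and relativization.** Band secants are averaged with the
   territory shares as weights — per draw, so that the 95% uncertainty
   interval (2.5%/97.5% quantiles) of the aggregate reflects the full
   joint posterior. Dividing by the species' mean observed territory
   number per included area-year gives the relative relationship that is
   comparable across species. Quantiles throughout the package use linear
   interpolation of order statistics (R's type 7); one rule, applied
   everywhere, documented here.

### Shape classification

Slopes are only meaningful for species whose curve is (mostly) monotone.
The classifier works analytically on the posterior-median cubic
coefficients: interior extrema are the sign-changing roots of
$\beta_1 + 2\beta_2 x + 3\beta_3 x^2$. A species is `monotone` if no
extremum lies inside the observed standardized-log-N range,
`near_monotone` if extrema exist inside the observed range but none inside
the central interval (15th-85th percentile of standardized log N — the
same anchors the secant uses, so a curve counts as "mostly monotone"
exactly when its extrema avoid the segment the secant summarizes), and
`non_monotone` otherwise. Only `non_monotone` species are refused a linear
relationship. A double root of the derivative (an inflection with zero
slope) is not an extremum and never blocks monotonicity. The analytic rule
is verified against a brute-force 10,001-point grid monotonicity scan on
random cubics. Classification is done once per species, on the median
curve, not per draw.

### Support calls and guild summaries

A species with a linear relationship is `negative_supported` when the 95%
uncertainty interval of its slope lies below zero, `positive_supported`
above zero, and `unsupported` otherwise. Guild summaries count these calls
per guild level on each of four axes (main habitat, nesting site,
migration distance, breeding-season food) and report them as integer
percentages of *all* species in the guild, rounded half away from zero —
the convention that reproduces reported shares such as 15/37 = 41%. The
single species outside the nesting guilds (the cuckoo case) is excluded
from the nesting axis only. In the cohort-wide tally, linear species are
split by the sign of the posterior-mean relative slope; an exact zero (a
measure-zero event) counts as negative, a deterministic tie-break.

## The synthetic survey

No bird-survey data ship with the package; every stage is exercised on a
seedable generator that emulates the statistical structure the analysis
assumes:

* **Landscape** ([generate_landscape()]): 1-km cells scattered on a grid
  (~40% occupancy), a spatially smooth elevation field (Gaussian-kernel
  smoothing, 4 km correlation range, 650 m smooth SD plus 250 m
  cell-level noise over 250-2800 m), and a log-normal N surface with a
  linear negative elevation trend on the log scale (-0.55 per 1000 m from
  ~28 kg N/ha/yr at the low end — the lowland-high/alpine-low gradient),
  plus equal shares of smooth spatial and iid log-scale noise (0.25 each).
  The equal split keeps two independently drawn surfaces near-uncorrelated
  at a few hundred areas, so the elevation-N dependence is governed by the
  explicit trend parameter alone. Habitat fractions come from a normalized
  gamma mixture with an implicit "other" class (so named fractions sum
  below 1); arable cover fades with elevation; 55% of areas carry
  farmland, and those receive N application proportional to farmland cover
  (~90 kg N/ha/yr at full cover), putting summed farmland N in the
  100-150 kg range against ~6-45 for deposition alone.
* **Species** ([generate_species()]): guild tallies are apportioned from
  the reference 112-species composition (largest-remainder rule, exact at
  112) or set explicitly; per-guild distributions for the cubic N
  coefficients define each species' true dose-response (default: declining
  in forest/settlement/wetland/several, increasing in alpine, hump-shaped
  in farmland). Intercepts, habitat coefficients, $\pi_0 \sim$ Beta(2, 5),
  $\phi \sim$ logNormal(log 1.5, 0.4) and $\sigma_y \sim |N(0, 0.12)|$
  are drawn to give realistic territory counts (a few per occupied area,
  ~25% structural zeros, marked overdispersion).
* **Counts** ([simulate_counts()]): the ZINB observation model run
  forward, with covariates standardized against the simulated areas' own
  distribution. The census process itself (three visits aggregated to
  territories) is *not* simulated — the model consumes territory counts,
  which is where the analysis starts.

What passing tests on these data do and do not show: they verify the
estimation and slope machinery recovers known truths under the model's own
assumptions, with the right false-support rate when N has no effect. They
cannot certify behaviour under real-data pathologies the generator omits —
measurement error in modelled N surfaces, spatially autocorrelated
residuals, observer effects, or habitat covariates correlated in ways the
gamma mixture does not produce.

## Problem sizes and numerical choices

The default synthetic scenario is 500 areas x 20 species x 5 years,
configurable up to a full survey scale of ~2100 x 112. The test suite's
simulation studies use 2,000 area-years per species for parameter-recovery
and calibration studies (40 recovery replicates; 200 zero-effect species
for the false-support rate) and a 20-species known-truth cohort at 400
areas x 5 years for the end-to-end check; these sizes give Monte-Carlo
error comfortably below the assertions' tolerances while keeping a
desk-scale run.

Numerical decisions, in one place: linear predictors and log-scale
parameters are clamped at ±30 before exponentiation so optimizer line
searches cannot underflow $\mu$ or $\phi$ to zero; the Hessian inverse
gets an escalating diagonal ridge if factorization fails; root-finding in
the shape classifier treats coefficients below 1e-12 as zero (degrading
the quadratic derivative to linear or constant); band edges must be
strictly ascending and default edges are clipped to the observed elevation
range; quantiles are type 7 everywhere; percentages round half away from
zero.

## Limitations

* No multispecies joint model (a per-species analysis is the deliberate
  design; a joint model is known to be fragile here), no spatial random
  fields, and no model selection machinery.
* The Laplace back end assumes a roughly Gaussian posterior; it is the
  right tool for screening many species quickly, while final inferences on
  ill-identified fits (few occupied areas, near-degenerate mixtures)
  should use the MCMC back end and heed its convergence flags.
* The elevation-band edges and the "mostly monotone" criterion are
  conventions exposed as configuration; results near classification
  boundaries can move between `near_monotone` and `non_monotone` under
  different central intervals.
* Correlation is not causation: the pipeline quantifies associations
  between N input and territory numbers under covariate adjustment; it
  has no design leverage to separate N from whatever tracks it.
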