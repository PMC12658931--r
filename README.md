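# birdNdep

Links atmospheric nitrogen (N) deposition to breeding-bird territory
numbers. Eutrophication from airborne N changes vegetation structure,
plant diversity and invertebrate food supply, and bird populations are
expected to respond — differently across ecological guilds. `birdNdep`
implements the full species-to-guild analysis for gridded 1-km
breeding-bird surveys, and ships a seedable synthetic-data generator so
the whole pipeline is testable without any survey download. It is written
for quantitative ecologists working with territory-mapping count data.

## The method

Per species, territory counts per survey area and year are modelled with a
Bayesian zero-inflated negative binomial:

    P(y = k) = pi0 * 1{k = 0} + (1 - pi0) * NB(k | mu, phi),
    log mu   = alpha + b1*xN + b2*xN^2 + b3*xN^3 + x'gamma + u_year,

with `xN` standardized log N deposition (deposition + agricultural
application for farmland species), habitat covariates `x` (elevation,
forest, arable, roads linear + quadratic; settlement; rocks/wetland/
shoreline as presence), a year random intercept, and variance
`mu + mu^2/phi` in the count process. Inclusion filters mirror the survey
design: a species needs at least 50 occupied areas, and only areas within
10 km of an occupied one enter its model.

Because a cubic's coefficients are not comparable across species, effect
sizes are extracted geometrically: per elevation band (six bands, bands
with < 5 areas dropped), the expected-territory curve over the band's
observed N range is evaluated per posterior draw; the slope of the secant
through the curve at the 15th and 85th N percentiles — per 10 kg N/ha/yr
(40 for farmland species) — is averaged across bands with the species'
territory shares as weights, and divided by its mean territory number for
a relative, cross-species-comparable slope. Averaging happens per draw, so
the 95% uncertainty interval carries the full posterior. Species whose
median curve has an extremum in the central N range get no linear
relationship; the rest are classified negative/positive, well-supported
when the interval excludes zero, and tallied by habitat, nesting,
migration and food guilds.

See `vignettes/nitrogen-territory-analysis.Rmd` for the complete
methodological account.

## Worked example

Simulate a 300-area, 12-species, 5-year survey and run the whole pipeline
with the deterministic Laplace back end:

```r
library(birdNdep)
cfg <- run_config(n_areas = 300, n_species = 12, years = 2012:2016,
                  draws = 800, seed = 20)
man <- run_pipeline(cfg)   # add out_dir = "run1" to write all CSVs
man$results[, c("species_id", "shape_class", "support",
                "rel_mean", "rel_lo", "rel_hi")]
#>    species_id   shape_class            support rel_mean  rel_lo  rel_hi
#> 1        S001 near_monotone negative_supported   -0.356 -0.9788 -0.1108
#> 2        S002      monotone negative_supported   -1.010 -2.1346 -0.3741
#> 3        S003  non_monotone          no_linear       NA      NA      NA
#> 4        S004 near_monotone negative_supported   -0.246 -0.6469 -0.0382
#> 5        S005      monotone        unsupported    0.106 -0.0875  0.3906
#> ...
```

`rel_mean` is the relative linear relationship: the change in expected
territories per +10 kg N/ha/yr (+40 for farmland species), as a fraction
of the species' mean territory number; `rel_lo`/`rel_hi` bound its 95%
uncertainty interval. `S003` has a hump-shaped response (extremum at
intermediate N), so no linear slope is reported for it. The cohort tally
and a guild summary:

```r
man$tally
#> $n_linear        9
#> $n_negative      8
#> $n_positive      1
#> $n_neg_supported 7
#> $n_pos_supported 0
#> $n_no_linear     3

man$guild_summaries$food
#>   guild_axis guild_level n_species n_linear n_no_linear n_neg_supported ...
#> 1       food insectivore         7        6           1               5
#> 2       food   herbivore         3        1           2               1
#> 3       food  vertebrate         1        1           0               0
#> 4       food    omnivore         1        1           0               1
```

Under the default generator truths (declining responses in forest,
settlement and wetland species, increasing in alpine, hump-shaped in
farmland), 8 of the 9 linear species come out negative and 7 of those are
well supported — the expected picture at this sample size.

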