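Package: birdNdep
Title: Nitrogen Deposition and Breeding-Bird Territory Numbers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links atmospheric nitrogen deposition to breeding-bird territory
    numbers with per-species Bayesian zero-inflated negative-binomial
    regressions that include a cubic effect of log nitrogen. Posterior draws
    are turned into effect curves per elevation band, percentile-secant
    slopes per 10 (or 40) kg N/ha/yr, and territory-weighted absolute and
    relative linear relationships with 95% uncertainty intervals, which are
    then classified by shape and support and aggregated into ecological-guild
    summaries. A seedable synthetic-data generator emulating a gridded 1-km
    breeding-bird survey makes every stage testable without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
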