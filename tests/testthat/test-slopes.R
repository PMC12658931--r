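test_that("band construction drops sparse bands and renormalizes shares", {
  # hand-built dataset view: 14 areas in two bands (10 + 4)
  at <- data.frame(area_id = sprintf("a%02d", 1:14),
                   x_km = 1:14, y_km = 1,
                   elevation_m = c(rep(400, 10), rep(800, 4)),
                   N = c(seq(10, 30, length.out = 10), 8, 9, 10, 11),
                   x_N = rnorm(14),
                   territories_total = c(rep(3, 10), rep(10, 4)))
  ds <- list(area_tab = at)
  b <- make_bands(ds, band_edges = c(300, 600, 1000))
  expect_equal(nrow(b), 1)              # 4-point band dropped
  expect_equal(b$territory_share, 1)    # renormalized to 1
  expect_equal(b$n_points, 10)
  expect_equal(b$N15, unname(quantile(seq(10, 30, length.out = 10), 0.15)))

  # both bands retained: shares follow summed territories 30 and 10
  at2 <- rbind(at[1:10, ],
               data.frame(area_id = sprintf("b%02d", 1:5), x_km = 15:19,
                          y_km = 1, elevation_m = seq(800, 850, by = 12.5),
                          N = c(8, 9, 10, 11, 14), x_N = 0,
                          territories_total = 2))
  b2 <- make_bands(list(area_tab = at2), c(300, 600, 1000))
  expect_equal(b2$territory_share, c(0.75, 0.25))
  expect_lt(abs(sum(b2$territory_share) - 1), 1e-12)

  expect_error(make_bands(list(area_tab = at), c(300, 300, 1000)),
               "ascending")
  # all bands dropped -> species unanalysable
  expect_error(make_bands(list(area_tab = at[1:4, ]), c(300, 600, 1000)),
               "unanalysable")
})

test_that("effect curves equal the hand-computed expected territory number", {
  s <- sim_species(100, 2012:2013, beta_N = c(-0.4, 0.1, 0), seed = 61)
  f <- fit_zinb(s$dataset, quick_cfg(draws = 200), seed = 17)
  bands <- make_bands(s$dataset)
  b1 <- bands[1, , drop = FALSE]
  cv <- effect_curve(f, s$dataset, b1, n_grid = 7)
  expect_equal(dim(cv$expected), c(200, 7))
  expect_true(all(cv$expected >= 0))
  # grid clipped to the band's observed N range
  expect_equal(range(cv$N_grid), c(b1$N_min, b1$N_max))

  # single-draw hand check at 3 grid points
  d <- f$draws[1, , drop = FALSE]
  rec <- s$dataset$std_record
  m <- rec$mean[rec$column == "x_N"]; sd_n <- rec$sd[rec$column == "x_N"]
  ze <- (b1$elev_median - rec$mean[rec$column == "elevation"]) /
    rec$sd[rec$column == "elevation"]
  pres <- vapply(c("rocks", "wetland", "shoreline"), function(cn) {
    as.numeric(mean(s$dataset$X[, cn]) >= 0.5)
  }, numeric(1))
  for (N in cv$N_grid[c(1, 4, 7)]) {
    x <- (log(N) - m) / sd_n
    eta <- d[, "alpha"] + d[, "beta_x_N"] * x + d[, "beta_x_N2"] * x^2 +
      d[, "beta_x_N3"] * x^3 + d[, "beta_elevation"] * ze +
      d[, "beta_elevation2"] * ze^2 +
      sum(d[, paste0("beta_", names(pres))] * pres)
    want <- (1 - plogis(d[, "logit_pi_zero"])) * exp(eta)
    expect_equal(predict(cv, N)[1, 1], unname(want), tolerance = 1e-10)
  }

  # no N effect -> flat curve for every draw
  f0 <- f
  f0$draws[, c("beta_x_N", "beta_x_N2", "beta_x_N3")] <- 0
  cv0 <- effect_curve(f0, s$dataset, b1, n_grid = 5)
  expect_equal(apply(cv0$expected, 1, function(r) diff(range(r))),
               rep(0, 200))
})

test_that("secant slopes reproduce analytic values", {
  band <- data.frame(N15 = 5, N85 = 25)
  # power-law curve f(N) = e^0.5 * N^0.2
  cv <- manual_curve(eta0 = 0.5, bN = c(0.2, 0, 0))
  got <- secant_slope(cv, band, scale_kg = 10)
  want <- (exp(0.5) * 25^0.2 - exp(0.5) * 5^0.2) / 20 * 10
  expect_equal(got, want, tolerance = 1e-10)
  expect_equal(round(got, 5), 0.43190)

  # linear curve f(N) = c * N: secant equals the slope for any percentiles
  cvl <- manual_curve(eta0 = log(0.7), bN = c(1, 0, 0))
  expect_equal(secant_slope(cvl, band, 10), 0.7 * 10, tolerance = 1e-12)
  expect_equal(secant_slope(cvl, data.frame(N15 = 8, N85 = 12), 40),
               0.7 * 40, tolerance = 1e-12)

  # constant curve -> slope 0
  cvc <- manual_curve(eta0 = 1.2, bN = c(0, 0, 0))
  expect_equal(secant_slope(cvc, band, 10), 0)

  expect_error(secant_slope(cv, data.frame(N15 = 5, N85 = 5), 10), "N85")
})

test_that("aggregation weights bands per draw and relativizes by the mean", {
  bands <- data.frame(territory_share = c(0.75, 0.25))
  slopes <- list(rep(-1.0, 4), rep(0.2, 4))
  agg <- aggregate_and_relativize(slopes, bands, mean_territories = 2,
                                  scale_kg = 10)
  expect_equal(agg$abs_draws, rep(-0.7, 4))
  expect_equal(agg$abs_mean, -0.7)
  expect_equal(agg$rel_mean, -0.35)

  # per-draw propagation: UI of transform == transform of per-draw values
  s1 <- c(-1.2, -0.8, -1.0, -0.6, -1.4)
  s2 <- c(0.3, 0.1, 0.2, 0.0, 0.4)
  agg2 <- aggregate_and_relativize(list(s1, s2), bands, 2, 10)
  expect_equal(agg2$abs_draws, 0.75 * s1 + 0.25 * s2)
  expect_equal(agg2$abs_ui95,
               unname(quantile(0.75 * s1 + 0.25 * s2, c(0.025, 0.975))))
  expect_equal(agg2$rel_ui95, agg2$abs_ui95 / 2)

  # rescaling counts and curves by c scales abs, leaves rel unchanged
  cc <- 3
  agg3 <- aggregate_and_relativize(lapply(list(s1, s2), `*`, cc), bands,
                                   2 * cc, 10)
  expect_equal(agg3$abs_draws, cc * agg2$abs_draws)
  expect_equal(agg3$rel_draws, agg2$rel_draws)

  expect_error(aggregate_and_relativize(list(s1, s2), bands, 0, 10),
               "positive")
  expect_error(aggregate_and_relativize(list(s1, s2[1:3]), bands, 2, 10),
               "draw count")
})

test_that("shape classification follows the extrema rule", {
  # pure linear term: derivative never zero
  expect_equal(classify_shape(mock_fit_bN(c(0.5, 0, 0)),
                              mock_ds_range(c(-2, 2), c(-1, 1))),
               "monotone")
  # derivative 1 - x^2: extrema at +/- 1
  b <- c(1, 0, -1 / 3)
  expect_equal(classify_shape(mock_fit_bN(b),
                              mock_ds_range(c(-0.5, 0.5), c(-0.4, 0.4))),
               "monotone")
  expect_equal(classify_shape(mock_fit_bN(b),
                              mock_ds_range(c(-2, 2), c(-0.8, 0.8))),
               "near_monotone")
  expect_equal(classify_shape(mock_fit_bN(b),
                              mock_ds_range(c(-2, 2), c(-1.2, 1.2))),
               "non_monotone")
  # hump at the centre of the range
  expect_equal(classify_shape(mock_fit_bN(c(0, -1, 0)),
                              mock_ds_range(c(-2, 2), c(-1, 1))),
               "non_monotone")
  # classification agrees with a grid monotonicity scan (small sweep; the
  # full 1000-cubic sweep runs in the acceptance suite)
  set.seed(19)
  for (i in 1:100) {
    bN <- rnorm(3)
    got <- classify_shape(mock_fit_bN(bN),
                          mock_ds_range(c(-2.5, 2.5), c(-1, 1)))
    expect_equal(got, scan_shape(bN, c(-2.5, 2.5), c(-1, 1)))
  }
})

test_that("species-level slope extraction ties the stages together", {
  s <- sim_species(250, 2012:2014, beta_N = c(-0.8, 0, 0), seed = 71)
  f <- fit_zinb(s$dataset, quick_cfg(), seed = 23)
  bands <- make_bands(s$dataset)
  r <- slope_for_species(f, s$dataset, bands, s$traits)
  expect_s3_class(r, "slope_result")
  expect_true(r$shape_class %in% c("monotone", "near_monotone"))
  expect_equal(r$support, "negative_supported")
  expect_equal(r$scale_kg, 10)
  expect_equal(r$rel_draws, r$abs_draws / r$mean_territories)
  # sign coherence: every draw-level band secant shares the negative sign
  expect_lt(r$abs_ui95[2], 0)
  df <- as.data.frame(r)
  expect_equal(df$rel_lo, r$rel_ui95[1])

  # hump-shaped truth with the peak mid-range -> no linear relationship
  sh <- sim_species(250, 2012:2014, beta_N = c(0, -0.9, 0), seed = 72)
  fh <- fit_zinb(sh$dataset, quick_cfg(), seed = 24)
  rh <- slope_for_species(fh, sh$dataset, make_bands(sh$dataset), sh$traits)
  expect_equal(rh$shape_class, "non_monotone")
  expect_equal(rh$support, "no_linear")
  expect_true(is.na(rh$rel_mean))

  # farmland species use the 40-kg slope unit
  sf <- sim_species(250, 2012:2014, beta_N = c(0.8, 0, 0),
                    habitat = "farmland", seed = 73)
  ff <- fit_zinb(sf$dataset, quick_cfg(), seed = 25)
  rf <- slope_for_species(ff, sf$dataset, make_bands(sf$dataset), sf$traits)
  expect_equal(rf$scale_kg, 40)
  expect_equal(rf$support, "positive_supported")
})
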