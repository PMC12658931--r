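test_that("landscape generation is deterministic and respects invariants", {
  a1 <- generate_landscape(100, seed = 1)
  a2 <- generate_landscape(100, seed = 1)
  expect_identical(a1, a2)
  a3 <- generate_landscape(100, seed = 2)
  expect_false(identical(a1, a3))

  fr <- a1[, c("forest", "arable", "grassland", "settlement")]
  expect_true(all(fr >= 0 & fr <= 1))
  expect_true(all(rowSums(fr) <= 1))
  expect_true(all(a1$roads >= 0 & a1$roads <= 1))
  expect_true(all(a1$n_deposition > 0))
  expect_false(anyNA(a1))
  # application positive exactly on farmland cover
  expect_true(all((a1$n_application > 0) ==
                    (a1$arable + a1$grassland > 0)))
  # N declines with elevation under the default configuration
  expect_lt(cor(a1$elevation_m, a1$n_deposition), -0.3)
})

test_that("landscape generation rejects degenerate inputs", {
  expect_error(generate_landscape(5, seed = 1), "n_areas")
  cfg <- landscape_config()
  cfg$elevation_range <- c(1000, 1000)
  expect_error(generate_landscape(50, cfg, seed = 1), "width")
})

test_that("zero elevation-N slope leaves elevation and N uncorrelated", {
  cfg <- landscape_config()
  cfg$n_elevation_slope <- 0
  a <- generate_landscape(500, cfg, seed = 3)
  expect_lt(abs(cor(a$elevation_m, a$n_deposition)), 0.2)
})

test_that("zero farmland fraction forces zero N application", {
  cfg <- landscape_config()
  cfg$farmland_fraction <- 0
  a <- generate_landscape(100, cfg, seed = 4)
  expect_true(all(a$n_application == 0))
  expect_true(all(a$arable == 0))
})

test_that("guild tallies follow the reference composition exactly", {
  sp <- generate_species(guild_config(), 112, seed = 5)
  food <- table(sp$traits$food_guild)
  expect_equal(as.integer(food[c("insectivore", "herbivore", "vertebrate",
                                 "omnivore")]), c(67, 24, 10, 11))
  habitat <- table(sp$traits$habitat_guild)
  expect_equal(as.integer(habitat[c("forest", "farmland", "settlement",
                                    "wetland", "alpine", "several")]),
               c(51, 19, 8, 12, 9, 13))
  nesting <- table(sp$traits$nesting_guild)
  expect_equal(as.integer(nesting[c("ground", "higher", "none")]),
               c(37, 74, 1))
  expect_equal(as.integer(table(sp$traits$migration_guild)[
    c("long", "short_resident")]), c(26, 86))
  # farmland / alpine flags track the habitat guild
  expect_identical(sp$traits$is_farmland,
                   sp$traits$habitat_guild == "farmland")
  expect_identical(sp$traits$is_alpine,
                   sp$traits$habitat_guild == "alpine")

  # new seed: different truths, identical tallies
  sp2 <- generate_species(guild_config(), 112, seed = 6)
  expect_equal(table(sp2$traits$food_guild), food)
  expect_false(identical(sp$truth$alpha, sp2$truth$alpha))
})

test_that("forced guild cells pin the N coefficients", {
  cfg <- list(food = list(insectivore = list(mean = c(-0.5, 0, 0),
                                             sd = c(0, 0, 0))))
  sp <- generate_species(cfg, 40, seed = 7)
  ins <- sp$traits$food_guild == "insectivore"
  expect_true(all(sp$truth$beta_N1[ins] == -0.5))
  expect_true(all(sp$truth$beta_N2[ins] == 0))
  expect_true(all(sp$truth$beta_N3[ins] == 0))
  expect_true(all(sp$truth$beta_N1[!ins] == 0))
  expect_error(generate_species(list(), 10, seed = 1), "non-empty")
})

test_that("count simulation matches the mixture's closed-form moments", {
  areas <- manual_areas(20)
  traits <- data.frame(species_id = "SP1", habitat_guild = "forest",
                       is_farmland = FALSE, is_alpine = FALSE,
                       stringsAsFactors = FALSE)
  mk_truth <- function(pi_zero, phi) {
    data.frame(species_id = "SP1", alpha = log(2), beta_N1 = 0,
               pi_zero = pi_zero, phi = phi, sigma_year = 0,
               stringsAsFactors = FALSE)
  }
  # degenerate mixture: everything zero
  tr1 <- mk_truth(1, 1)
  c1 <- simulate_counts(areas, list(traits = traits, truth = tr1), 1:5, 1)
  expect_true(all(c1$territories == 0))

  # Poisson limit: phi huge, no zero inflation -> mean/variance ratio ~ 1
  tr2 <- mk_truth(0, 1e6)
  c2 <- simulate_counts(areas, list(traits = traits, truth = tr2),
                        1:2500, seed = 2)  # 50,000 draws
  y2 <- c2$territories
  expect_lt(abs(var(y2) / mean(y2) - 1), 0.1)

  # mixture mean (1 - 0.3) * 2 = 1.4 within 2% at 100,000 draws
  tr3 <- mk_truth(0.3, 1.5)
  c3 <- simulate_counts(areas, list(traits = traits, truth = tr3),
                        1:5000, seed = 3)
  expect_lt(abs(mean(c3$territories) - 1.4) / 1.4, 0.02)
  # mixture variance: (1-pi)(mu + mu^2/phi) + pi(1-pi) mu^2
  v <- 0.7 * (2 + 4 / 1.5) + 0.3 * 0.7 * 4
  expect_lt(abs(var(c3$territories) - v) / v, 0.05)

  # determinism
  expect_identical(c3, simulate_counts(areas, list(traits = traits,
                                                   truth = tr3), 1:5000, 3))

  # unknown covariate in the truth is rejected
  tr4 <- mk_truth(0.2, 1)
  tr4$beta_bogus <- 1
  expect_error(simulate_counts(areas, list(traits = traits, truth = tr4),
                               1:2, 1), "absent")
})
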