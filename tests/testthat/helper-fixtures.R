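# Shared fixtures and independent oracles. Oracles are written from the
# closed-form definitions, never through package internals.

# ZINB pmf by direct formula (binomial-coefficient form).
oracle_zinb_pmf <- function(k, mu, phi, pi_zero) {
  nb <- exp(lgamma(k + phi) - lgamma(phi) - lgamma(k + 1) +
              phi * (log(phi) - log(phi + mu)) +
              k * (log(mu) - log(phi + mu)))
  (k == 0) * pi_zero + (1 - pi_zero) * nb
}

# Minimal survey-area table with hand-set values (bypasses the landscape
# generator for targeted covariate tests).
manual_areas <- function(n = 12, seed = 1) {
  set.seed(seed)
  data.frame(
    area_id = sprintf("M%03d", seq_len(n)),
    x_km = seq_len(n), y_km = rep(1, n),
    elevation_m = seq(300, 2400, length.out = n),
    n_deposition = exp(rnorm(n, log(15), 0.4)),
    n_application = c(rep(0, n %/% 2), runif(n - n %/% 2, 20, 80)),
    forest = runif(n, 0, 0.6), arable = runif(n, 0, 0.3),
    grassland = runif(n, 0, 0.3), settlement = runif(n, 0, 0.1),
    roads = runif(n, 0, 0.1),
    rocks_amt = rep(c(0, 0, 3.2, 0.1), length.out = n),
    wetland_amt = rep(c(0, 1.5), length.out = n),
    shoreline_amt = rep(c(0, 0, 0.7), length.out = n),
    stringsAsFactors = FALSE
  )
}

# One synthetic species with fully controlled truth, plus its model-ready
# dataset (all areas included; covariates other than N have zero effect).
sim_species <- function(n_areas, years, beta_N = c(0, 0, 0),
                        alpha = log(2), pi_zero = 0.25, phi = 1.5,
                        sigma_year = 0.1, habitat = "forest", seed) {
  areas <- generate_landscape(n_areas, seed = seed)
  traits <- data.frame(
    species_id = "SP1", habitat_guild = habitat,
    nesting_guild = "ground", migration_guild = "long",
    food_guild = "insectivore",
    is_farmland = habitat == "farmland", is_alpine = habitat == "alpine",
    stringsAsFactors = FALSE
  )
  truth <- data.frame(species_id = "SP1", alpha = alpha,
                      beta_N1 = beta_N[1], beta_N2 = beta_N[2],
                      beta_N3 = beta_N[3], pi_zero = pi_zero, phi = phi,
                      sigma_year = sigma_year, stringsAsFactors = FALSE)
  counts <- simulate_counts(areas, list(traits = traits, truth = truth),
                            years, seed = seed + 1)
  list(areas = areas, traits = traits, truth = truth, counts = counts,
       dataset = build_design(areas, counts, traits))
}

# Mock fit and dataset for the shape classifier (constant draws).
mock_fit_bN <- function(bN, D = 5) {
  list(draws = matrix(rep(bN, each = D), D, 3,
                      dimnames = list(NULL, c("beta_x_N", "beta_x_N2",
                                              "beta_x_N3"))))
}
mock_ds_range <- function(range, central) {
  list(area_tab = data.frame(x_N = range), logN_q = central)
}

# Grid-scan shape oracle: monotone on the full observed range, else
# monotone on the central interval, else non-monotone.
scan_shape <- function(bN, range, central, n = 10001) {
  is_mono <- function(lo, hi) {
    x <- seq(lo, hi, length.out = n)
    d <- diff(bN[1] * x + bN[2] * x^2 + bN[3] * x^3)
    all(d >= 0) || all(d <= 0)
  }
  if (is_mono(range[1], range[2])) return("monotone")
  if (is_mono(central[1], central[2])) return("near_monotone")
  "non_monotone"
}

# Hand-built effect curve on the model's curve family:
# f(N) = (1 - pi) * exp(eta0 + b1 x + b2 x^2 + b3 x^3), x = (log N - m)/s.
manual_curve <- function(eta0, bN, pi_zero = 0, logN_mean = 0, logN_sd = 1,
                         N_range = c(5, 25), D = 1) {
  structure(list(band_id = 1L,
                 N_grid = seq(N_range[1], N_range[2], length.out = 25),
                 eta0 = rep(eta0, D),
                 bN = matrix(rep(bN, each = D), D, 3),
                 pi_zero = rep(pi_zero, D),
                 logN_mean = logN_mean, logN_sd = logN_sd),
            class = "effect_curve")
}

quick_cfg <- function(draws = 500) fit_config(draws = draws)
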