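# Synthetic survey-design generator: gridded 1-km survey areas with an
# elevation-structured nitrogen surface, guild-structured species with known
# N-response curves, and zero-inflated negative-binomial territory counts.

#' Default landscape configuration
#'
#' Parameters of the synthetic landscape: the elevation field, the nitrogen
#' deposition surface (log-normal base, linear negative elevation trend on
#' the log scale, smooth spatial noise), the habitat mixture and the
#' agricultural N application model. Units are metres for elevation,
#' kilometres for coordinates and kg N/ha/yr for nitrogen.
#'
#' @return Named list of landscape parameters.
#' @export
landscape_config <- function() {
  list(
    elevation_range    = c(250, 2800),  # m a.s.l.
    elevation_sd       = 650,           # SD of the smooth elevation field (m)
    elevation_noise_sd = 250,           # iid cell-level elevation noise (m)
    n_log_intercept    = log(28),       # log kg N/ha/yr at the low end
    n_elevation_slope  = -0.55,         # per 1000 m climb, log scale
    n_spatial_sd       = 0.25,          # smooth spatial field, log scale
    n_noise_sd         = 0.25,          # iid lognormal noise
    spatial_range_km   = 4,             # Gaussian smoothing bandwidth
    farmland_fraction  = 0.55,          # share of areas with any farmland
    application_rate   = 90,            # kg N/ha/yr at full farmland cover
    p_zero_rocks       = 0.80,          # share of areas with amount == 0
    p_zero_wetland     = 0.85,
    p_zero_shoreline   = 0.90
  )
}

# Smooth a white-noise vector over the grid with a Gaussian kernel and
# rescale to unit variance, giving a spatially autocorrelated field.
.smooth_field <- function(x_km, y_km, range_km, seed_noise) {
  d2 <- outer(x_km, x_km, "-")^2 + outer(y_km, y_km, "-")^2
  w <- exp(-d2 / (2 * range_km^2))
  f <- drop(w %*% seed_noise) / rowSums(w)
  s <- stats::sd(f)
  if (s < .Machine$double.eps) return(rep(0, length(f)))
  (f - mean(f)) / s
}

#' Generate a synthetic survey landscape
#'
#' Places `n_areas` 1-km grid cells, draws a spatially smooth elevation
#' field, a nitrogen-deposition surface that declines with elevation, a
#' habitat mixture (fractions of forest, arable, grassland, settlement and
#' roads) and mostly-zero amounts of rocks, wetland and shoreline.
#' Agricultural N application is positive exactly on areas with farmland
#' cover and scales with that cover.
#'
#' @param n_areas Number of survey areas (>= 10).
#' @param config Landscape parameters, see [landscape_config()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A data frame with one row per area: `area_id`, `x_km`, `y_km`,
#'   `elevation_m`, `n_deposition`, `n_application`, habitat fractions
#'   `forest`, `arable`, `grassland`, `settlement`, `roads`, and raw amounts
#'   `rocks_amt`, `wetland_amt`, `shoreline_amt`.
#' @export
generate_landscape <- function(n_areas, config = landscape_config(), seed) {
  if (!is.numeric(n_areas) || length(n_areas) != 1L || n_areas < 10) {
    stop("`n_areas` must be a single number >= 10")
  }
  n_areas <- as.integer(n_areas)
  seed <- .assert_count_seed(seed)
  er <- config$elevation_range
  if (length(er) != 2L || !(er[2] > er[1])) {
    stop("`config$elevation_range` must have positive width")
  }
  set.seed(seed)

  # distinct cells on a square grid roughly 40% occupied, like a scattered
  # national survey sample
  side <- ceiling(sqrt(n_areas / 0.4))
  cells <- sample.int(side * side, n_areas)
  x_km <- (cells - 1L) %% side + 0.5
  y_km <- (cells - 1L) %/% side + 0.5

  elev_field <- .smooth_field(x_km, y_km, config$spatial_range_km,
                              stats::rnorm(n_areas))
  elevation <- mean(er) + config$elevation_sd * elev_field +
    stats::rnorm(n_areas, 0, config$elevation_noise_sd)
  elevation <- pmin(pmax(elevation, er[1]), er[2])

  n_field <- .smooth_field(x_km, y_km, config$spatial_range_km,
                           stats::rnorm(n_areas))
  log_n <- config$n_log_intercept +
    config$n_elevation_slope * (elevation - er[1]) / 1000 +
    config$n_spatial_sd * n_field +
    stats::rnorm(n_areas, 0, config$n_noise_sd)
  n_deposition <- exp(log_n)

  # habitat mixture: gamma weights normalized together with an implicit
  # "other" class, which keeps the four named fractions summing below one;
  # arable cover fades out with elevation
  has_farm <- stats::runif(n_areas) < config$farmland_fraction
  g_forest <- stats::rgamma(n_areas, shape = 2.0, rate = 1)
  g_arable <- stats::rgamma(n_areas, shape = 1.2, rate = 1) *
    exp(-(elevation - er[1]) / 700) * has_farm
  g_grass <- stats::rgamma(n_areas, shape = 1.5, rate = 1) * has_farm
  g_settle <- stats::rgamma(n_areas, shape = 0.5, rate = 1) *
    exp(-(elevation - er[1]) / 900)
  g_other <- stats::rgamma(n_areas, shape = 1.5, rate = 1)
  tot <- g_forest + g_arable + g_grass + g_settle + g_other
  forest <- g_forest / tot
  arable <- g_arable / tot
  grassland <- g_grass / tot
  settlement <- g_settle / tot
  roads <- stats::rbeta(n_areas, 1.5, 40)

  farm_cover <- arable + grassland
  n_application <- ifelse(
    farm_cover > 0,
    config$application_rate * farm_cover * stats::rlnorm(n_areas, 0, 0.2),
    0
  )

  amt <- function(p_zero, shape, scale) {
    nz <- stats::runif(n_areas) >= p_zero
    ifelse(nz, stats::rgamma(n_areas, shape = shape, scale = scale), 0)
  }
  rocks_amt <- amt(config$p_zero_rocks, 1.2, 2)
  wetland_amt <- amt(config$p_zero_wetland, 1.0, 1.5)
  shoreline_amt <- amt(config$p_zero_shoreline, 1.0, 1.0)

  data.frame(
    area_id = sprintf("A%04d", seq_len(n_areas)),
    x_km = x_km, y_km = y_km,
    elevation_m = elevation,
    n_deposition = n_deposition,
    n_application = n_application,
    forest = forest, arable = arable, grassland = grassland,
    settlement = settlement, roads = roads,
    rocks_amt = rocks_amt, wetland_amt = wetland_amt,
    shoreline_amt = shoreline_amt,
    stringsAsFactors = FALSE
  )
}

# Reference guild composition of the 112-species cohort used for
# proportional designs: habitat, nesting site, migration distance, food.
.guild_reference <- list(
  habitat = c(forest = 51, farmland = 19, settlement = 8, wetland = 12,
              alpine = 9, several = 13),
  nesting = c(ground = 37, higher = 74, none = 1),
  migration = c(long = 26, short_resident = 86),
  food = c(insectivore = 67, herbivore = 24, vertebrate = 10, omnivore = 11)
)

.guild_levels <- lapply(.guild_reference, names)

# Largest-remainder apportionment of reference proportions to n species.
.apportion <- function(ref_counts, n) {
  quota <- ref_counts / sum(ref_counts) * n
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Default guild configuration for N-response truths
#'
#' Each configured guild cell supplies a Normal distribution (mean and SD)
#' for the three coefficients of the cubic in standardized log N
#' (`beta_N1`, `beta_N2`, `beta_N3`). A species' coefficients are the sum of
#' draws from every configured cell it belongs to; the default keys on the
#' habitat axis only: declining responses in forest, settlement, wetland and
#' mixed-habitat species, an increasing response in alpine species, and a
#' hump-shaped response in farmland species.
#'
#' @return Nested list `config[[axis]][[level]] = list(mean, sd)`.
#' @export
guild_config <- function() {
  list(
    habitat = list(
      forest     = list(mean = c(-0.40, 0.00, 0), sd = c(0.15, 0.05, 0.02)),
      farmland   = list(mean = c(0.25, -0.35, 0), sd = c(0.10, 0.10, 0.02)),
      settlement = list(mean = c(-0.30, 0.00, 0), sd = c(0.15, 0.05, 0.02)),
      wetland    = list(mean = c(-0.30, 0.00, 0), sd = c(0.15, 0.05, 0.02)),
      alpine     = list(mean = c(0.35, 0.00, 0),  sd = c(0.15, 0.05, 0.02)),
      several    = list(mean = c(-0.20, 0.00, 0), sd = c(0.15, 0.05, 0.02))
    )
  )
}

#' Generate guild-structured species traits and ground truths
#'
#' Assigns every species one level on each of the four guild axes (main
#' habitat, nesting site, migration distance, breeding-season food) with
#' tallies apportioned from the reference 112-species composition — or from
#' an explicit `design` — and draws per-species true model parameters:
#' intercept, habitat coefficients, the cubic N coefficients from
#' `guild_config`, zero-inflation probability, negative-binomial dispersion
#' and the between-year SD. Farmland species are flagged `is_farmland`
#' (their N variable is deposition plus application, slopes per 40 kg) and
#' alpine species `is_alpine` (arable covariates excluded when modelling).
#'
#' @param guild_config Nested list of per-guild N-coefficient distributions,
#'   see [guild_config()]. Must be non-empty.
#' @param n_species Number of species (>= 1).
#' @param seed Integer seed.
#' @param design Optional named list overriding guild tallies per axis, e.g.
#'   `list(habitat = c(forest = 10, alpine = 5, farmland = 5))`. Counts must
#'   sum to `n_species`; axes not listed use the reference proportions.
#' @return List with data frames `traits` (`species_id`, the four
#'   `*_guild` columns, `is_farmland`, `is_alpine`) and `truth`
#'   (`species_id`, `alpha`, `beta_*` columns, `pi_zero`, `phi`,
#'   `sigma_year`). Guild tallies depend only on `n_species` and `design`,
#'   never on the seed.
#' @export
generate_species <- function(guild_config, n_species, seed, design = NULL) {
  if (!is.list(guild_config) || length(guild_config) == 0L) {
    stop("`guild_config` must be a non-empty list")
  }
  if (!is.numeric(n_species) || length(n_species) != 1L || n_species < 1) {
    stop("`n_species` must be a single positive integer")
  }
  n_species <- as.integer(n_species)
  seed <- .assert_count_seed(seed)
  bad_axes <- setdiff(names(guild_config), names(.guild_levels))
  if (length(bad_axes)) {
    stop("unknown guild axis in config: ", paste(bad_axes, collapse = ", "))
  }
  set.seed(seed)

  assign_axis <- function(axis) {
    ref <- .guild_reference[[axis]]
    if (!is.null(design[[axis]])) {
      cnt <- design[[axis]]
      if (is.null(names(cnt)) || !all(names(cnt) %in% names(ref))) {
        stop("`design$", axis, "` must be named with valid guild levels")
      }
      if (sum(cnt) != n_species) {
        stop("`design$", axis, "` counts must sum to n_species")
      }
      labels <- rep(names(cnt), cnt)
    } else {
      labels <- rep(names(ref), .apportion(ref, n_species))
    }
    sample(labels)  # shuffle; tallies unchanged
  }
  traits <- data.frame(
    species_id = sprintf("S%03d", seq_len(n_species)),
    habitat_guild = assign_axis("habitat"),
    nesting_guild = assign_axis("nesting"),
    migration_guild = assign_axis("migration"),
    food_guild = assign_axis("food"),
    stringsAsFactors = FALSE
  )
  traits$is_farmland <- traits$habitat_guild == "farmland"
  traits$is_alpine <- traits$habitat_guild == "alpine"

  habitat_beta_names <- c("elevation", "elevation2", "forest", "forest2",
                          "arable", "arable2", "roads", "roads2",
                          "settlement", "rocks", "wetland", "shoreline")
  habitat_beta_sd <- c(0.30, 0.12, 0.25, 0.10, 0.20, 0.08, 0.15, 0.06,
                       0.20, 0.15, 0.15, 0.15)

  truth <- data.frame(species_id = traits$species_id,
                      alpha = stats::rnorm(n_species, log(1.2), 0.6),
                      stringsAsFactors = FALSE)
  bh <- matrix(stats::rnorm(n_species * length(habitat_beta_names), 0,
                            rep(habitat_beta_sd, each = n_species)),
               n_species, length(habitat_beta_names))
  colnames(bh) <- paste0("beta_", habitat_beta_names)
  bh[traits$is_alpine, c("beta_arable", "beta_arable2")] <- 0

  bN <- matrix(0, n_species, 3)
  for (axis in names(guild_config)) {
    cells <- guild_config[[axis]]
    level <- traits[[paste0(axis, "_guild")]]
    for (i in seq_len(n_species)) {
      cell <- cells[[level[i]]]
      if (!is.null(cell)) {
        bN[i, ] <- bN[i, ] + stats::rnorm(3, cell$mean, cell$sd)
      }
    }
  }
  colnames(bN) <- c("beta_N1", "beta_N2", "beta_N3")

  truth <- cbind(truth, as.data.frame(bN), as.data.frame(bh))
  truth$pi_zero <- stats::rbeta(n_species, 2, 5)
  truth$phi <- stats::rlnorm(n_species, log(1.5), 0.4)
  truth$sigma_year <- abs(stats::rnorm(n_species, 0, 0.12))
  list(traits = traits, truth = truth)
}

# Standardized design columns shared by the simulator and the model builder.
# `n_var` is the species' N variable on the kg scale. Returns the matrix,
# the standardization record, and the standardized log-N vector.
.design_columns <- function(areas, n_var) {
  if (any(!is.finite(n_var)) || any(n_var <= 0)) {
    stop("N variable must be positive and finite in every area")
  }
  stdz <- function(x) {
    m <- mean(x); s <- stats::sd(x)
    list(z = if (s > 0) (x - m) / s else x * 0, mean = m, sd = s)
  }
  log_n <- log(n_var)
  zN <- stdz(log_n)
  ze <- stdz(areas$elevation_m)
  zf <- stdz(areas$forest)
  za <- stdz(areas$arable)
  zr <- stdz(areas$roads)
  zs <- stdz(areas$settlement)
  X <- cbind(
    x_N = zN$z, x_N2 = zN$z^2, x_N3 = zN$z^3,
    elevation = ze$z, elevation2 = ze$z^2,
    forest = zf$z, forest2 = zf$z^2,
    arable = za$z, arable2 = za$z^2,
    roads = zr$z, roads2 = zr$z^2,
    settlement = zs$z,
    rocks = as.numeric(areas$rocks_amt > 0),
    wetland = as.numeric(areas$wetland_amt > 0),
    shoreline = as.numeric(areas$shoreline_amt > 0)
  )
  record <- data.frame(
    column = colnames(X),
    base = c("log_N", "log_N", "log_N", "elevation_m", "elevation_m",
             "forest", "forest", "arable", "arable", "roads", "roads",
             "settlement", "rocks_amt", "wetland_amt", "shoreline_amt"),
    power = c(1, 2, 3, 1, 2, 1, 2, 1, 2, 1, 2, 1, 1, 1, 1),
    kind = c(rep("continuous", 12), rep("presence", 3)),
    mean = c(rep(zN$mean, 3), rep(ze$mean, 2), rep(zf$mean, 2),
             rep(za$mean, 2), rep(zr$mean, 2), zs$mean, NA, NA, NA),
    sd = c(rep(zN$sd, 3), rep(ze$sd, 2), rep(zf$sd, 2),
           rep(za$sd, 2), rep(zr$sd, 2), zs$sd, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  list(X = X, record = record, x_N = zN$z)
}

#' Simulate territory counts from known species truths
#'
#' Runs the zero-inflated negative-binomial observation model forward: for
#' each species, the expected territory number per area is
#' `mu = exp(alpha + x'beta + u_year)` on covariates standardized with the
#' simulated areas' own means and SDs, year effects `u_year` are drawn once
#' per species and year from `Normal(0, sigma_year)`, and each count is 0
#' with probability `pi_zero` or else negative binomial with mean `mu` and
#' dispersion `phi` (variance `mu + mu^2/phi`). Farmland species respond to
#' deposition plus application; all others to deposition alone.
#'
#' @param areas Landscape from [generate_landscape()].
#' @param species List with `traits` and `truth`, from [generate_species()].
#' @param years Integer vector of survey years (non-empty).
#' @param seed Integer seed.
#' @return Data frame of `area_id`, `species_id`, `year`, `territories` with
#'   one row per area x species x year.
#' @export
simulate_counts <- function(areas, species, years, seed) {
  if (length(years) == 0L) stop("`years` must be non-empty")
  seed <- .assert_count_seed(seed)
  traits <- species$traits
  truth <- species$truth
  beta_cols <- grep("^beta_", names(truth), value = TRUE)
  n_a <- nrow(areas)

  # two N variables, standardized against their own distribution
  dep <- .design_columns(areas, areas$n_deposition)
  farm <- .design_columns(areas, areas$n_deposition + areas$n_application)

  nmap <- c(N1 = "x_N", N2 = "x_N2", N3 = "x_N3")
  col_names <- vapply(beta_cols, function(b) {
    nm <- sub("^beta_", "", b)
    if (nm %in% names(nmap)) nmap[[nm]] else nm
  }, character(1))
  missing <- setdiff(col_names, colnames(dep$X))
  if (length(missing)) {
    stop("species truths reference covariates absent from areas: ",
         paste(missing, collapse = ", "))
  }

  set.seed(seed)
  out <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    X <- if (traits$is_farmland[i]) farm$X else dep$X
    beta <- as.numeric(truth[i, beta_cols])
    eta0 <- truth$alpha[i] + drop(X[, col_names, drop = FALSE] %*% beta)
    u <- stats::rnorm(length(years), 0, truth$sigma_year[i])
    recs <- vector("list", length(years))
    for (j in seq_along(years)) {
      mu <- exp(pmin(eta0 + u[j], 30))
      zero <- stats::runif(n_a) < truth$pi_zero[i]
      y <- ifelse(zero, 0L,
                  stats::rnbinom(n_a, size = truth$phi[i], mu = mu))
      recs[[j]] <- data.frame(area_id = areas$area_id,
                              species_id = truth$species_id[i],
                              year = years[j], territories = y,
                              stringsAsFactors = FALSE)
    }
    out[[i]] <- do.call(rbind, recs)
  }
  counts <- do.call(rbind, out)
  rownames(counts) <- NULL
  counts
}
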