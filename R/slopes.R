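# From posterior draws to per-elevation-band effect curves, percentile
# secant slopes, territory-weighted linear relationships with full
# posterior propagation, and a shape classification.

#' Default elevation band edges
#'
#' Six bands spanning the breeding elevations in the data: the observed
#' minimum, 600, 1000, 1400, 1800 and 2200 m, and the observed maximum
#' (inner edges outside the observed range are dropped).
#'
#' @param elevation_m Observed elevations of the included areas.
#' @return Strictly ascending numeric vector of band edges.
#' @export
default_band_edges <- function(elevation_m) {
  lo <- min(elevation_m); hi <- max(elevation_m)
  if (!(hi > lo)) stop("zero elevation spread; cannot form bands")
  inner <- c(600, 1000, 1400, 1800, 2200)
  c(lo, inner[inner > lo & inner < hi], hi)
}

#' Assign included areas to elevation bands
#'
#' Partitions the species' included areas into elevation bands (intervals
#' closed on the left, open on the right, last closed), drops bands with
#' fewer than `min_points` areas or without any spread in observed N, and
#' computes per band the observed N range, the 15th/85th N percentiles and
#' the species' territory share (observed territories summed over years,
#' renormalized over retained bands).
#'
#' @param dataset A `species_dataset`.
#' @param band_edges Strictly ascending edge vector (default:
#'   [default_band_edges()] on the included areas).
#' @param min_points Minimum areas per retained band, default 5.
#' @return Data frame of class `elevation_bands`, one row per retained
#'   band: `band_id`, `lower_m`, `upper_m`, `n_points`, `elev_median`,
#'   `N_min`, `N_max`, `N15`, `N85`, `territory_share`; member area ids in
#'   `attr(, "members")`.
#' @export
make_bands <- function(dataset, band_edges = NULL, min_points = 5) {
  at <- dataset$area_tab
  if (is.null(band_edges)) band_edges <- default_band_edges(at$elevation_m)
  if (length(band_edges) < 2L || any(diff(band_edges) <= 0)) {
    stop("`band_edges` must be strictly ascending")
  }
  band <- findInterval(at$elevation_m, band_edges, rightmost.closed = TRUE)
  rows <- lapply(seq_len(length(band_edges) - 1L), function(b) {
    idx <- which(band == b)
    if (length(idx) < min_points) return(NULL)
    N <- at$N[idx]
    q <- .quantile7(N, c(0.15, 0.85))
    if (!(q[2] > q[1])) return(NULL)  # no usable N spread
    list(df = data.frame(band_id = b,
                         lower_m = band_edges[b],
                         upper_m = band_edges[b + 1L],
                         n_points = length(idx),
                         elev_median = stats::median(at$elevation_m[idx]),
                         N_min = min(N), N_max = max(N),
                         N15 = q[1], N85 = q[2],
                         territory_share = sum(at$territories_total[idx])),
         members = at$area_id[idx])
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    stop("all elevation bands dropped; species unanalysable")
  }
  out <- do.call(rbind, lapply(rows, `[[`, "df"))
  tot <- sum(out$territory_share)
  if (tot <= 0) stop("species has no territories in retained bands")
  out$territory_share <- out$territory_share / tot
  rownames(out) <- NULL
  attr(out, "members") <- lapply(rows, `[[`, "members")
  class(out) <- c("elevation_bands", "data.frame")
  out
}

#' Effect curve of expected territories versus N for one band
#'
#' Evaluates, for every posterior draw, the expected territory number
#' `(1 - pi_zero) * exp(alpha + x'beta)` along an N grid clipped to the
#' band's observed N range. Continuous covariates other than N sit at their
#' species-specific means, presence covariates at their most frequent
#' level, the elevation terms at the band's median member elevation
#' (standardized with the stored record), and the year effect at 0.
#'
#' @param fit A `zinb_fit`.
#' @param dataset The matching `species_dataset`.
#' @param band One row of [make_bands()] output.
#' @param n_grid Number of grid points (>= 2).
#' @return Object of class `effect_curve` with `N_grid`, the draws x grid
#'   matrix `expected`, and what is needed to evaluate the curve exactly at
#'   any N inside the band (see [predict.effect_curve()]).
#' @export
effect_curve <- function(fit, dataset, band, n_grid = 100) {
  if (n_grid < 2) stop("`n_grid` must be at least 2")
  if (nrow(band) != 1L) stop("`band` must be a single band row")
  rec <- dataset$std_record
  X <- dataset$X
  n_cols <- c("x_N", "x_N2", "x_N3")

  profile <- numeric(ncol(X))
  names(profile) <- colnames(X)
  for (cn in colnames(X)) {
    r <- rec[rec$column == cn, ]
    if (cn %in% n_cols) next               # varies along the grid
    if (r$kind == "presence") {
      profile[cn] <- as.numeric(mean(X[, cn]) >= 0.5)  # most frequent level
    } else if (r$base == "elevation_m") {
      z <- (band$elev_median - r$mean) / r$sd
      profile[cn] <- z^r$power
    } else {
      profile[cn] <- 0  # species mean of a standardized covariate
    }
  }

  d <- fit$draws
  beta_cols <- paste0("beta_", colnames(X))
  non_n <- setdiff(colnames(X), n_cols)
  eta0 <- d[, "alpha"] +
    if (length(non_n)) {
      drop(d[, paste0("beta_", non_n), drop = FALSE] %*% profile[non_n])
    } else 0
  bN <- sapply(n_cols, function(cn) {
    bc <- paste0("beta_", cn)
    if (bc %in% colnames(d)) d[, bc] else numeric(nrow(d))
  })
  r_n <- rec[rec$column == "x_N", ]

  curve <- structure(list(
    band_id = band$band_id,
    N_grid = seq(band$N_min, band$N_max, length.out = n_grid),
    eta0 = eta0, bN = bN,
    pi_zero = stats::plogis(d[, "logit_pi_zero"]),
    logN_mean = r_n$mean, logN_sd = r_n$sd
  ), class = "effect_curve")
  curve$expected <- predict(curve, curve$N_grid)
  curve
}

#' Evaluate an effect curve exactly at given N values
#'
#' @param object An `effect_curve`.
#' @param N N values (kg N/ha/yr) at which to evaluate.
#' @param ... Unused.
#' @return Draws x length(N) matrix of expected territory numbers.
#' @export
predict.effect_curve <- function(object, N, ...) {
  x <- (log(N) - object$logN_mean) / object$logN_sd
  eta <- outer(object$eta0, rep(1, length(N))) +
    object$bN[, 1] %o% x + object$bN[, 2] %o% x^2 + object$bN[, 3] %o% x^3
  (1 - object$pi_zero) * exp(pmin(eta, 30))
}

#' Percentile secant slope of an effect curve
#'
#' For each posterior draw, the slope of the straight line through the
#' curve's values at the band's 15th and 85th N percentiles (evaluated
#' exactly, not interpolated from the grid), expressed per `scale_kg`
#' kg N/ha/yr.
#'
#' @param curve An `effect_curve`.
#' @param band The band row the curve was built for.
#' @param scale_kg Slope unit: 10 for most species, 40 for farmland species.
#' @return Numeric vector of per-draw slopes (territories per area per
#'   `scale_kg` kg N/ha/yr).
#' @export
secant_slope <- function(curve, band, scale_kg = 10) {
  if (!(band$N85 > band$N15)) {
    stop("N85 must exceed N15 for a secant slope")
  }
  f <- predict(curve, c(band$N15, band$N85))
  (f[, 2] - f[, 1]) / (band$N85 - band$N15) * scale_kg
}

#' Territory-weighted absolute and relative linear relationships
#'
#' Averages per-band secant slopes across elevation bands using the
#' species' territory shares as weights — per posterior draw, so model
#' uncertainty propagates into the result — and divides by the species'
#' mean territory number for the relative relationship. Uncertainty
#' intervals are the 2.5% and 97.5% quantiles of the per-draw values.
#'
#' @param band_slopes List of per-draw slope vectors, one per retained
#'   band, all the same length.
#' @param bands The [make_bands()] table (weights must sum to 1).
#' @param mean_territories Mean observed territory number per included
#'   area-year (> 0).
#' @param scale_kg Slope unit the inputs are expressed in.
#' @return List with `abs_draws`, `abs_mean`, `abs_ui95`, `rel_draws`,
#'   `rel_mean`, `rel_ui95`, `scale_kg`.
#' @export
aggregate_and_relativize <- function(band_slopes, bands, mean_territories,
                                     scale_kg = 10) {
  if (length(band_slopes) != nrow(bands)) {
    stop("one slope vector per retained band is required")
  }
  D <- unique(lengths(band_slopes))
  if (length(D) != 1L) stop("band slope vectors differ in draw count")
  w <- bands$territory_share
  if (abs(sum(w) - 1) > 1e-8) stop("band weights must sum to 1")
  if (!is.finite(mean_territories) || mean_territories <= 0) {
    stop("`mean_territories` must be positive")
  }
  S <- do.call(cbind, band_slopes)
  abs_draws <- drop(S %*% w)
  rel_draws <- abs_draws / mean_territories
  list(abs_draws = abs_draws,
       abs_mean = mean(abs_draws),
       abs_ui95 = .quantile7(abs_draws, c(0.025, 0.975)),
       rel_draws = rel_draws,
       rel_mean = mean(rel_draws),
       rel_ui95 = .quantile7(rel_draws, c(0.025, 0.975)),
       scale_kg = scale_kg)
}

# Interior extrema of the cubic b1*x + b2*x^2 + b3*x^3: roots of the
# derivative where the derivative changes sign.
.cubic_extrema <- function(b1, b2, b3, tol = 1e-12) {
  a <- 3 * b3; b <- 2 * b2; c0 <- b1
  if (abs(a) < tol) {
    if (abs(b) < tol) return(numeric(0))  # constant derivative
    return(-c0 / b)                        # linear derivative: sign change
  }
  disc <- b^2 - 4 * a * c0
  if (disc <= tol) return(numeric(0))      # double root: no sign change
  s <- sqrt(disc)
  sort(c((-b - s) / (2 * a), (-b + s) / (2 * a)))
}

#' Classify the shape of the N effect curve
#'
#' Uses the posterior-median cubic coefficients on the standardized-log-N
#' scale. The curve is `monotone` when no interior extremum of the cubic
#' falls inside the observed standardized-log-N range of the included
#' areas, `near_monotone` when extrema exist inside the observed range but
#' none inside the central interval (15th to 85th percentile of
#' standardized log N over all included areas), and `non_monotone`
#' otherwise. Only `non_monotone` species are denied a linear relationship.
#'
#' @param fit A `zinb_fit` (cubic N terms present).
#' @param dataset The matching `species_dataset`.
#' @return One of `"monotone"`, `"near_monotone"`, `"non_monotone"`.
#' @export
classify_shape <- function(fit, dataset) {
  d <- fit$draws
  bmed <- vapply(c("beta_x_N", "beta_x_N2", "beta_x_N3"), function(cn) {
    if (cn %in% colnames(d)) stats::median(d[, cn]) else 0
  }, numeric(1))
  ext <- .cubic_extrema(bmed[1], bmed[2], bmed[3])
  rng <- range(dataset$area_tab$x_N)
  central <- dataset$logN_q
  in_range <- ext[ext > rng[1] & ext < rng[2]]
  if (length(in_range) == 0L) return("monotone")
  in_central <- in_range[in_range >= central[1] & in_range <= central[2]]
  if (length(in_central) == 0L) return("near_monotone")
  "non_monotone"
}

#' Linear relationship of territory numbers with N for one species
#'
#' Runs the full slope extraction: shape classification first; species with
#' a non-monotone curve get no linear relationship (`support =
#' "no_linear"`). Otherwise per-band effect curves and percentile secant
#' slopes (per 40 kg N/ha/yr for farmland species, per 10 otherwise) are
#' aggregated with territory-share weights and relativized by the mean
#' observed territory number per included area-year. The support call uses
#' the 95% uncertainty interval: `negative_supported` when its upper end is
#' below 0, `positive_supported` when its lower end is above 0, otherwise
#' `unsupported`.
#'
#' @param fit A `zinb_fit`.
#' @param dataset The matching `species_dataset`.
#' @param bands Output of [make_bands()].
#' @param traits The species' traits entry (`is_farmland` drives the slope
#'   unit).
#' @param n_grid Grid points per effect curve.
#' @return Object of class `slope_result`; see [as.data.frame.slope_result()].
#' @export
slope_for_species <- function(fit, dataset, bands, traits, n_grid = 100) {
  traits <- as.list(traits)
  shape <- classify_shape(fit, dataset)
  base <- list(species_id = dataset$species_id, shape_class = shape,
               n_bands = nrow(bands),
               mean_territories = mean(dataset$response$territories))
  if (shape == "non_monotone") {
    return(structure(c(base, list(
      support = "no_linear", scale_kg = NA_real_,
      abs_draws = NULL, rel_draws = NULL,
      abs_mean = NA_real_, abs_ui95 = c(NA_real_, NA_real_),
      rel_mean = NA_real_, rel_ui95 = c(NA_real_, NA_real_)
    )), class = "slope_result"))
  }
  scale_kg <- if (isTRUE(traits$is_farmland)) 40 else 10
  band_slopes <- lapply(seq_len(nrow(bands)), function(b) {
    cv <- effect_curve(fit, dataset, bands[b, , drop = FALSE], n_grid)
    secant_slope(cv, bands[b, , drop = FALSE], scale_kg)
  })
  agg <- aggregate_and_relativize(band_slopes, bands,
                                  base$mean_territories, scale_kg)
  band_summary <- data.frame(
    species_id = dataset$species_id, band_id = bands$band_id,
    lower_m = bands$lower_m, upper_m = bands$upper_m,
    n_points = bands$n_points, N15 = bands$N15, N85 = bands$N85,
    weight = bands$territory_share,
    slope_mean = vapply(band_slopes, mean, numeric(1)),
    stringsAsFactors = FALSE)
  base$band_summary <- band_summary
  support <- if (agg$rel_ui95[2] < 0) {
    "negative_supported"
  } else if (agg$rel_ui95[1] > 0) {
    "positive_supported"
  } else {
    "unsupported"
  }
  structure(c(base, list(support = support, scale_kg = scale_kg), agg),
            class = "slope_result")
}

#' Flatten a slope result to one data-frame row
#'
#' @param x A `slope_result`.
#' @param ... Unused.
#' @return One-row data frame with means, interval bounds, shape class,
#'   support call, slope unit and band count.
#' @export
as.data.frame.slope_result <- function(x, ...) {
  data.frame(species_id = x$species_id,
             shape_class = x$shape_class,
             support = x$support,
             scale_kg = x$scale_kg,
             n_bands = x$n_bands,
             mean_territories = x$mean_territories,
             abs_mean = x$abs_mean,
             abs_lo = x$abs_ui95[1], abs_hi = x$abs_ui95[2],
             rel_mean = x$rel_mean,
             rel_lo = x$rel_ui95[1], rel_hi = x$rel_ui95[2],
             stringsAsFactors = FALSE)
}

#' @export
print.slope_result <- function(x, ...) {
  cat("<slope_result> ", x$species_id, ": ", x$shape_class, " / ",
      x$support, "\n", sep = "")
  if (!is.na(x$rel_mean)) {
    cat(sprintf("  rel slope %.4f [%.4f, %.4f] per %g kg N/ha/yr\n",
                x$rel_mean, x$rel_ui95[1], x$rel_ui95[2], x$scale_kg))
  }
  invisible(x)
}
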