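# Posterior predictive checks, randomized-quantile residuals and a
# semivariogram-based screen for residual spatial autocorrelation.

# Linear predictor matrix (draws x observations) for a fit/dataset pair.
.eta_draws <- function(fit, dataset, rows = NULL) {
  d <- fit$draws
  if (!is.null(rows)) d <- d[rows, , drop = FALSE]
  beta_cols <- paste0("beta_", colnames(dataset$X))
  eta <- d[, "alpha"] +
    tcrossprod(d[, beta_cols, drop = FALSE], dataset$X)
  if (length(dataset$years)) {
    ye <- d[, paste0("year_eff_", dataset$years), drop = FALSE]
    eta <- eta + ye[, dataset$year_index, drop = FALSE]
  }
  pmin(eta, 30)
}

# ZINB cdf at k (vectorized over k, mu; scalar phi/pi).
.zinb_cdf <- function(k, mu, phi, pi_zero) {
  ifelse(k < 0, 0, pi_zero + (1 - pi_zero) *
           stats::pnbinom(pmax(k, 0), size = phi, mu = mu))
}

#' Empirical semivariogram
#'
#' Classical (Matheron) semivariogram of point values over distance bins:
#' half the mean squared difference between all pairs whose separation
#' falls in the bin.
#'
#' @param x,y Point coordinates (km).
#' @param values Numeric values at the points.
#' @param n_bins Number of equal-width distance bins up to half the maximum
#'   pairwise distance.
#' @return Data frame with `dist` (bin midpoint), `gamma` and `n_pairs`.
#' @export
semivariogram <- function(x, y, values, n_bins = 8) {
  d <- sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
  dv <- 0.5 * outer(values, values, "-")^2
  lt <- lower.tri(d)
  dd <- d[lt]; gg <- dv[lt]
  dmax <- max(dd) / 2
  breaks <- seq(0, dmax, length.out = n_bins + 1)
  bin <- cut(dd, breaks, include.lowest = TRUE, labels = FALSE)
  ok <- !is.na(bin)
  gamma <- tapply(gg[ok], bin[ok], mean)
  npair <- tapply(gg[ok], bin[ok], length)
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  idx <- as.integer(names(gamma))
  data.frame(dist = mid[idx], gamma = as.numeric(gamma),
             n_pairs = as.numeric(npair))
}

#' Posterior predictive and residual diagnostics
#'
#' Draws replicated count datasets from the fitted model, compares the zero
#' fraction, mean, maximum and variance of the observed counts with their
#' replicated distributions (posterior predictive p-values, midpoint rule
#' for ties), computes randomized-quantile residuals with the ZINB cdf
#' averaged over draws, and screens for spatial autocorrelation with an
#' empirical semivariogram of per-area mean residuals.
#'
#' @param fit A `zinb_fit`.
#' @param dataset The `species_dataset` the model was fitted to.
#' @param seed Integer seed for replicate draws and residual randomization.
#' @param n_rep Number of posterior predictive replicates.
#' @param resid_draws Number of draws averaged in the residual cdf.
#' @param n_bins Semivariogram distance bins.
#' @return Object of class `zinb_diagnostics`: `ppc` table, `residuals`
#'   (per observation) and `semivariogram` table.
#' @export
diagnose_fit <- function(fit, dataset, seed = 1, n_rep = 200,
                         resid_draws = 50, n_bins = 8) {
  seed <- .assert_count_seed(seed)
  set.seed(seed)
  y <- dataset$response$territories
  n <- length(y)
  D <- nrow(fit$draws)
  rows <- sample.int(D, n_rep, replace = n_rep > D)
  eta <- .eta_draws(fit, dataset, rows)
  phi <- exp(fit$draws[rows, "log_phi"])
  pz <- stats::plogis(fit$draws[rows, "logit_pi_zero"])

  stat_fun <- list(zero_fraction = function(v) mean(v == 0),
                   mean = mean, max = max, variance = stats::var)
  obs <- vapply(stat_fun, function(f) f(y), numeric(1))
  reps <- matrix(NA_real_, n_rep, length(stat_fun),
                 dimnames = list(NULL, names(stat_fun)))
  for (r in seq_len(n_rep)) {
    mu <- exp(eta[r, ])
    zero <- stats::runif(n) < pz[r]
    y_rep <- ifelse(zero, 0, stats::rnbinom(n, size = phi[r], mu = mu))
    reps[r, ] <- vapply(stat_fun, function(f) f(y_rep), numeric(1))
  }
  pval <- vapply(names(stat_fun), function(s) {
    mean(reps[, s] > obs[s]) + 0.5 * mean(reps[, s] == obs[s])
  }, numeric(1))
  ppc <- data.frame(statistic = names(stat_fun), observed = obs,
                    replicate_mean = colMeans(reps), p_value = pval,
                    row.names = NULL)

  # randomized-quantile residuals, cdf averaged over draws
  rr <- seq_len(min(resid_draws, D))
  eta_r <- .eta_draws(fit, dataset, rr)
  phi_r <- exp(fit$draws[rr, "log_phi"])
  pz_r <- stats::plogis(fit$draws[rr, "logit_pi_zero"])
  Fhi <- Flo <- matrix(0, length(rr), n)
  for (r in seq_along(rr)) {
    mu <- exp(eta_r[r, ])
    Fhi[r, ] <- .zinb_cdf(y, mu, phi_r[r], pz_r[r])
    Flo[r, ] <- .zinb_cdf(y - 1, mu, phi_r[r], pz_r[r])
  }
  flo <- colMeans(Flo); fhi <- colMeans(Fhi)
  u <- stats::runif(n, flo, fhi)
  resid <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
  residuals <- data.frame(area_id = dataset$response$area_id,
                          year = dataset$response$year, residual = resid)

  per_area <- tapply(resid, dataset$area_index, mean)
  at <- dataset$area_tab
  sv <- semivariogram(at$x_km, at$y_km, as.numeric(per_area), n_bins)

  structure(list(ppc = ppc, residuals = residuals, semivariogram = sv),
            class = "zinb_diagnostics")
}

#' @export
print.zinb_diagnostics <- function(x, ...) {
  cat("<zinb_diagnostics>\n")
  print(x$ppc, row.names = FALSE)
  invisible(x)
}
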