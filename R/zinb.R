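# Bayesian zero-inflated negative-binomial territory model with year
# random intercepts. Two inference back ends share one contract: MAP plus
# Laplace-approximation draws (fast, deterministic given a seed) and
# adaptive random-walk MCMC.

#' Zero-inflated negative-binomial log pmf
#'
#' Log probability of `k` territories under the mixture that emits 0 with
#' probability `pi_zero` and otherwise a negative-binomial count with mean
#' `mu` and dispersion `phi` (variance `mu + mu^2/phi`), evaluated stably in
#' log space. Arguments recycle to a common length.
#'
#' @param k Non-negative integer counts.
#' @param mu Positive means.
#' @param phi Positive dispersions.
#' @param pi_zero Zero-inflation probabilities in \[0, 1\].
#' @return Vector of log probabilities.
#' @export
zinb_logpmf <- function(k, mu, phi, pi_zero) {
  if (any(!is.finite(k)) || any(k < 0) || any(k != floor(k))) {
    stop("`k` must contain non-negative integers")
  }
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("`mu` must be positive")
  if (any(!is.finite(phi)) || any(phi <= 0)) stop("`phi` must be positive")
  if (any(!is.finite(pi_zero)) || any(pi_zero < 0) || any(pi_zero > 1)) {
    stop("`pi_zero` must lie in [0, 1]")
  }
  n <- max(length(k), length(mu), length(phi), length(pi_zero))
  k <- rep_len(k, n); mu <- rep_len(mu, n)
  phi <- rep_len(phi, n); pi_zero <- rep_len(pi_zero, n)

  out <- log1p(-pi_zero) + stats::dnbinom(k, size = phi, mu = mu, log = TRUE)
  is0 <- k == 0
  if (any(is0)) {
    a <- log(pi_zero[is0])      # point mass at zero
    b <- out[is0]               # count-process zero
    both_inf <- !is.finite(a) & !is.finite(b)
    res <- .logaddexp(a, b)
    res[both_inf] <- -Inf
    out[is0] <- res
  }
  out
}

#' Default weakly informative priors
#'
#' Priors on the unconstrained sampling scale: Normal(0, 2.5) on
#' standardized coefficients, Student-t(3, 0, 2.5) on the intercept,
#' Logistic(0, 1) on the logit of the zero-inflation probability (uniform on
#' the probability), Exponential(1) on the dispersion `phi` (with log-scale
#' Jacobian), half-Normal(0, 1) on the between-year SD (with log-scale
#' Jacobian), and standard Normal on the non-centred year effects.
#'
#' @return Named list of prior hyperparameters.
#' @export
default_priors <- function() {
  list(beta_sd = 2.5, alpha_df = 3, alpha_scale = 2.5,
       sigma_year_sd = 1, phi_rate = 1)
}

# --- parameter vector layout: alpha, beta[K], logit_pi, log_phi,
#     log_sigma, z[Y] (non-centred year effects) ---------------------------

.par_dim <- function(K, Y) K + 4L + Y

.unpack <- function(theta, K, Y) {
  list(alpha = theta[1L],
       beta = theta[1L + seq_len(K)],
       logit_pi = theta[K + 2L],
       log_phi = theta[K + 3L],
       log_sigma = theta[K + 4L],
       z = if (Y > 0) theta[K + 4L + seq_len(Y)] else numeric(0))
}

.par_names <- function(beta_names, years) {
  c("alpha", paste0("beta_", beta_names), "logit_pi_zero", "log_phi",
    "log_sigma_year", if (length(years)) paste0("z_year_", years))
}

.zinb_loglik_theta <- function(theta, dd) {
  p <- .unpack(theta, dd$K, dd$Y)
  if (dd$n == 0L) return(0)
  sigma <- exp(pmin(p$log_sigma, 30))
  u <- sigma * p$z
  eta <- p$alpha + (if (dd$K > 0) drop(dd$X %*% p$beta) else 0) +
    (if (dd$Y > 0) u[dd$year_index] else 0)
  # clamp to keep mu and phi inside (0, Inf) through optimizer line searches
  mu <- exp(pmin(pmax(eta, -30), 30))
  phi <- exp(pmin(pmax(p$log_phi, -30), 30))
  sum(zinb_logpmf(dd$y, mu, phi, stats::plogis(p$logit_pi)))
}

.zinb_logprior_theta <- function(theta, K, Y, priors) {
  p <- .unpack(theta, K, Y)
  lp <- stats::dt(p$alpha / priors$alpha_scale, df = priors$alpha_df,
                  log = TRUE) - log(priors$alpha_scale)
  if (K > 0) lp <- lp + sum(stats::dnorm(p$beta, 0, priors$beta_sd, TRUE))
  lp <- lp + stats::dlogis(p$logit_pi, 0, 1, log = TRUE)
  # phi ~ Exponential(rate); density in log_phi includes Jacobian phi
  lp <- lp + stats::dexp(exp(p$log_phi), priors$phi_rate, log = TRUE) +
    p$log_phi
  # sigma ~ half-Normal(0, sd); Jacobian sigma
  sigma <- exp(p$log_sigma)
  lp <- lp + log(2) + stats::dnorm(sigma, 0, priors$sigma_year_sd, TRUE) +
    p$log_sigma
  if (Y > 0) lp <- lp + sum(stats::dnorm(p$z, 0, 1, log = TRUE))
  lp
}

# Internal data view used by the likelihood.
.fit_data <- function(dataset) {
  y <- dataset$response$territories
  list(y = y, X = dataset$X, year_index = dataset$year_index,
       n = length(y), K = ncol(dataset$X), Y = length(dataset$years))
}

.params_to_theta <- function(params, K, Y) {
  beta <- params$beta %||% numeric(K)
  if (length(beta) != K) stop("`params$beta` has wrong length")
  z <- params$z_year %||% numeric(Y)
  if (length(z) != Y) stop("`params$z_year` has wrong length")
  c(params$alpha, beta, params$logit_pi_zero, params$log_phi,
    params$log_sigma_year, z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log posterior density of the territory model
#'
#' Sum of the zero-inflated negative-binomial log likelihood over all
#' area-years — with `mu = exp(alpha + x'beta + year_effect)` and year
#' effects `sigma_year * z_year` — and the log priors (including the
#' standard-Normal density of the non-centred year effects and the
#' log-scale Jacobians for `phi` and `sigma_year`). An empty dataset
#' returns the prior alone.
#'
#' @param params Named list: `alpha`, `beta` (length = `ncol(dataset$X)`),
#'   `logit_pi_zero`, `log_phi`, `log_sigma_year`, `z_year` (one per year).
#' @param dataset A `species_dataset` from [build_design()].
#' @param priors See [default_priors()].
#' @return Scalar log posterior density (unnormalized).
#' @seealso [log_prior()] for the prior component alone.
#' @export
log_posterior <- function(params, dataset, priors = default_priors()) {
  dd <- .fit_data(dataset)
  theta <- .params_to_theta(params, dd$K, dd$Y)
  .zinb_loglik_theta(theta, dd) +
    .zinb_logprior_theta(theta, dd$K, dd$Y, priors)
}

#' Log prior density of the territory model parameters
#'
#' @inheritParams log_posterior
#' @return Scalar log prior density.
#' @export
log_prior <- function(params, dataset, priors = default_priors()) {
  dd <- .fit_data(dataset)
  theta <- .params_to_theta(params, dd$K, dd$Y)
  .zinb_logprior_theta(theta, dd$K, dd$Y, priors)
}

#' Sampler configuration
#'
#' @param method `"map_laplace"` (posterior mode plus Gaussian-approximation
#'   draws; deterministic given the seed) or `"mcmc"` (adaptive random-walk
#'   Metropolis started at the mode with the Laplace covariance as proposal
#'   shape).
#' @param draws Number of posterior draws to return (>= 100 recommended for
#'   downstream quantiles).
#' @param chains MCMC chains.
#' @param iter MCMC iterations per chain (first half discarded as warmup).
#' @param maxit Optimizer iteration cap.
#' @param rhat_max Convergence threshold on split-chain scale reduction.
#' @return Configuration list for [fit_zinb()].
#' @export
fit_config <- function(method = c("map_laplace", "mcmc"), draws = 1000,
                       chains = 2, iter = 4000, maxit = 1000,
                       rhat_max = 1.05) {
  list(method = match.arg(method), draws = draws, chains = chains,
       iter = iter, maxit = maxit, rhat_max = rhat_max)
}

.map_optimize <- function(dd, priors, maxit) {
  negpost <- function(theta) {
    v <- .zinb_loglik_theta(theta, dd) +
      .zinb_logprior_theta(theta, dd$K, dd$Y, priors)
    if (!is.finite(v)) 1e10 else -v
  }
  ybar <- mean(dd$y)
  start <- c(log(ybar + 0.1), numeric(dd$K), stats::qlogis(0.2), 0,
             log(0.1), numeric(dd$Y))
  opt <- stats::optim(start, negpost, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12),
                      hessian = TRUE)
  sigma <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(sigma)) {
    sigma <- solve(opt$hessian + diag(1e-6, length(start)))
  }
  sigma <- (sigma + t(sigma)) / 2
  list(mode = opt$par, vcov = sigma, lp = -opt$value,
       converged = opt$convergence == 0)
}

# Split-chain potential scale reduction factor, one value per parameter.
.split_rhat <- function(chains_list) {
  halves <- list()
  for (ch in chains_list) {
    n <- nrow(ch)
    h <- floor(n / 2)
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[(n - h + 1):n, , drop = FALSE]))
  }
  m <- length(halves)
  n <- nrow(halves[[1]])
  vapply(seq_len(ncol(halves[[1]])), function(j) {
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vars <- vapply(halves, function(h) stats::var(h[, j]), numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' Fit the territory model to one species
#'
#' @param dataset A `species_dataset` from [build_design()].
#' @param config Sampler settings from [fit_config()].
#' @param seed Integer seed; identical seed and config give identical draws.
#' @param priors See [default_priors()].
#' @return An object of class `zinb_fit` holding a draws matrix (columns
#'   `alpha`, `beta_*`, `logit_pi_zero`, `log_phi`, `sigma_year`,
#'   `year_eff_*`) and `meta` with sampler diagnostics. Non-convergence is
#'   flagged in `meta$converged`, never silently dropped.
#' @export
fit_zinb <- function(dataset, config = fit_config(), seed,
                     priors = default_priors()) {
  seed <- .assert_count_seed(seed)
  dd <- .fit_data(dataset)
  if (dd$n == 0L) stop("dataset has no observations")
  map <- .map_optimize(dd, priors, config$maxit)
  p <- .par_dim(dd$K, dd$Y)

  meta <- list(seed = seed, method = config$method, draws = config$draws,
               mode_log_posterior = map$lp, optimizer_converged = map$converged)

  if (config$method == "map_laplace") {
    set.seed(seed)
    theta_draws <- .rmvnorm(config$draws, map$mode, map$vcov)
    meta$converged <- map$converged
  } else {
    logpost <- function(theta) {
      v <- .zinb_loglik_theta(theta, dd) +
        .zinb_logprior_theta(theta, dd$K, dd$Y, priors)
      if (is.finite(v)) v else -Inf
    }
    prop_chol <- chol((2.38^2 / p) * (map$vcov + diag(1e-10, p)))
    chains_out <- vector("list", config$chains)
    acc <- numeric(config$chains)
    for (ch in seq_len(config$chains)) {
      set.seed(.child_seed(seed, ch))
      cur <- drop(.rmvnorm(1, map$mode, map$vcov))
      lp_cur <- logpost(cur)
      keep <- matrix(NA_real_, config$iter, p)
      n_acc <- 0
      for (it in seq_len(config$iter)) {
        prop <- cur + drop(stats::rnorm(p) %*% prop_chol)
        lp_prop <- logpost(prop)
        if (log(stats::runif(1)) < lp_prop - lp_cur) {
          cur <- prop; lp_cur <- lp_prop; n_acc <- n_acc + 1
        }
        keep[it, ] <- cur
      }
      acc[ch] <- n_acc / config$iter
      chains_out[[ch]] <- keep[(floor(config$iter / 2) + 1):config$iter, ,
                               drop = FALSE]
    }
    rhat <- .split_rhat(chains_out)
    pooled <- do.call(rbind, chains_out)
    idx <- unique(round(seq(1, nrow(pooled),
                            length.out = min(config$draws, nrow(pooled)))))
    theta_draws <- pooled[idx, , drop = FALSE]
    meta$acceptance <- acc
    meta$rhat_max <- max(rhat)
    meta$converged <- map$converged && max(rhat) <= config$rhat_max
    if (!meta$converged) {
      meta$warning <- "convergence diagnostics above threshold"
    }
  }

  beta_names <- colnames(dataset$X)
  draws <- matrix(NA_real_, nrow(theta_draws),
                  dd$K + 4L + dd$Y)
  colnames(draws) <- c("alpha", paste0("beta_", beta_names),
                       "logit_pi_zero", "log_phi", "sigma_year",
                       if (dd$Y > 0) paste0("year_eff_", dataset$years))
  draws[, "alpha"] <- theta_draws[, 1L]
  if (dd$K > 0) {
    draws[, 1L + seq_len(dd$K)] <- theta_draws[, 1L + seq_len(dd$K)]
  }
  draws[, "logit_pi_zero"] <- theta_draws[, dd$K + 2L]
  draws[, "log_phi"] <- theta_draws[, dd$K + 3L]
  sig <- exp(theta_draws[, dd$K + 4L])
  draws[, "sigma_year"] <- sig
  if (dd$Y > 0) {
    draws[, dd$K + 4L + seq_len(dd$Y)] <-
      sig * theta_draws[, dd$K + 4L + seq_len(dd$Y), drop = FALSE]
  }

  structure(list(draws = draws, species_id = dataset$species_id,
                 beta_names = beta_names, years = dataset$years,
                 mode = map$mode, vcov = map$vcov, meta = meta),
            class = "zinb_fit")
}

#' Posterior draws of the zero-inflation probability
#' @param fit A `zinb_fit`.
#' @return Numeric vector in (0, 1), one value per draw.
#' @export
draw_pi_zero <- function(fit) stats::plogis(fit$draws[, "logit_pi_zero"])

#' Posterior draws of the negative-binomial dispersion
#' @param fit A `zinb_fit`.
#' @return Positive numeric vector, one value per draw.
#' @export
draw_phi <- function(fit) exp(fit$draws[, "log_phi"])

#' @export
print.zinb_fit <- function(x, ...) {
  cat("<zinb_fit> ", x$species_id, " (", x$meta$method, ", ",
      nrow(x$draws), " draws)\n", sep = "")
  cat("  converged: ", isTRUE(x$meta$converged), "\n", sep = "")
  invisible(x)
}
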