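#' @keywords internal
"_PACKAGE"

# Quantile rule fixed package-wide: linear interpolation between order
# statistics (type 7). Every percentile in the pipeline goes through here.
.quantile7 <- function(x, probs) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7)
}

#' Round percentages half away from zero
#'
#' Integer rounding with ties going away from zero (so 41.5 -> 42 and
#' -41.5 -> -42), the convention used for all reported guild percentages.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# log(exp(a) + exp(b)) elementwise, stable for very negative inputs.
.logaddexp <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf would give NaN; that pair cannot arise in the mixture pmf
  m + log(exp(a - m) + exp(b - m))
}

# Draws from N(mean, sigma) via Cholesky; ridge jitter if sigma is not PD.
.rmvnorm <- function(n, mean, sigma, jitter = 1e-8) {
  p <- length(mean)
  ch <- NULL
  for (k in 0:8) {
    ridge <- if (k == 0) 0 else jitter * 10^(k - 1) * mean(diag(sigma))
    ch <- tryCatch(chol(sigma + diag(ridge, p)), error = function(e) NULL)
    if (!is.null(ch)) break
  }
  if (is.null(ch)) stop("covariance matrix could not be factorized")
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% ch, 2, mean, "+")
}

.assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}

.assert_count_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  as.integer(seed)
}

# Derive a stream-specific child seed that stays inside 32-bit range.
.child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647)
}
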