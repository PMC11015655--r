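# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Derive a child seed from a parent seed, stable and < 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1009L + as.integer(k) * 7919L) %% 2147483629L
}

# Sample skewness (g1) and kurtosis (b2, not excess).
skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) return(3)
  mean((x - m)^4) / v^2
}

# Standardised mean difference between two groups (pooled SD denominator).
std_mean_diff <- function(x, group, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  ok <- is.finite(x) & !is.na(group)
  x <- x[ok]; group <- group[ok]; w <- w[ok]
  g1 <- group; g0 <- !group
  m1 <- weighted.mean(x[g1], w[g1])
  m0 <- weighted.mean(x[g0], w[g0])
  v1 <- weighted.mean((x[g1] - m1)^2, w[g1])
  v0 <- weighted.mean((x[g0] - m0)^2, w[g0])
  (m1 - m0) / sqrt((v1 + v0) / 2)
}

# Solve a logistic intercept so that mean(plogis(b0 + lp)) == target.
solve_intercept <- function(lp, target) {
  f <- function(b0) mean(plogis(b0 + lp)) - target
  uniroot(f, lower = -30, upper = 30, tol = 1e-10)$root
}

# HC1 heteroskedasticity-robust covariance for a least-squares fit.
# X: model matrix used for the covariance bread; resid: residuals used for
# the meat (for 2SLS these are computed from the *original* exposure);
# w: optional case weights (probability weights, IPW-style).
hc1_vcov <- function(X, resid, w = NULL) {
  n <- nrow(X); k <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  XtXinv <- chol2inv(chol(crossprod(X * sqrt(w))))
  meat <- crossprod(X * (w * resid))
  vc <- XtXinv %*% meat %*% XtXinv
  vc * n / (n - k)
}

# Map a standard-normal latent to a shifted log-normal with the requested raw
# mean and SD (shift 1, floored at 0): raw = exp(mu + sigma*z) - 1.
latent_to_skewed <- function(z, mean_raw, sd_raw) {
  m <- mean_raw + 1
  s2 <- log(1 + (sd_raw / m)^2)
  mu <- log(m) - s2 / 2
  pmax(exp(mu + sqrt(s2) * z) - 1, 0)
}
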