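#' Choose a normalising transformation for a raw symptom scale
#'
#' Raw symptom counts are non-negative and right-skewed. Among the identity,
#' `log(y + 1)` and `sqrt(y)` candidates, the one minimising absolute sample
#' skewness is chosen, with absolute excess kurtosis (`|kurtosis - 3|`) as
#' the tie-break; the label of the winner is recorded so downstream tables
#' can report the scale in use.
#'
#' @param y Non-negative numeric vector of raw scores.
#' @param tie_tol Skewness difference below which two candidates are treated
#'   as tied and kurtosis decides.
#' @return List with `y` (transformed values) and `transform`
#'   (`"identity"`, `"log"` or `"sqrt"`).
#' @examples
#' select_transform(rexp(500))$transform
#' @export
select_transform <- function(y, tie_tol = 1e-8) {
  if (any(y < 0, na.rm = TRUE)) abort("`y` must be non-negative.")
  if (sd(y, na.rm = TRUE) == 0) {
    warn("Constant outcome; keeping the identity transform.")
    return(list(y = y, transform = "identity"))
  }
  cand <- list(identity = y, log = log1p(y), sqrt = sqrt(y))
  sk <- vapply(cand, function(v) abs(skewness(v)), double(1))
  ku <- vapply(cand, function(v) abs(kurtosis(v) - 3), double(1))
  best <- which(sk <= min(sk) + tie_tol)
  pick <- names(best)[which.min(ku[best])]
  list(y = cand[[pick]], transform = pick)
}

#' Standardise a numeric vector to z-scores
#'
#' @param y Numeric vector with positive variance (`NA`s are ignored for the
#'   mean/SD and preserved in place).
#' @return `(y - mean) / sd`, with mean 0 and sample SD 1.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(y) {
  s <- sd(y, na.rm = TRUE)
  if (!is.finite(s) || s == 0) abort("Cannot standardise a constant vector.")
  (y - mean(y, na.rm = TRUE)) / s
}

# shared guts for (weighted) least squares with optional HC1 robust SEs.
ols_fit <- function(y, X, weights = NULL, robust = FALSE) {
  qx <- if (is.null(weights)) qr(X) else qr(X * sqrt(weights))
  if (qx$rank < ncol(X)) {
    drop_idx <- qx$pivot[(qx$rank + 1):ncol(X)]
    warn(paste0("Dropping collinear terms: ",
                paste(colnames(X)[drop_idx], collapse = ", ")))
    X <- X[, -drop_idx, drop = FALSE]
  }
  fit <- if (is.null(weights)) lm.fit(X, y) else {
    stats::lm.wfit(X, y, weights)
  }
  beta <- fit$coefficients
  res <- y - drop(X %*% beta)
  n <- nrow(X); k <- ncol(X)
  if (robust || !is.null(weights)) {
    vc <- hc1_vcov(X, res, weights)
  } else {
    sig2 <- sum(res^2) / (n - k)
    vc <- chol2inv(chol(crossprod(X))) * sig2
  }
  list(beta = beta, vcov = vc, residuals = res, n = n, k = k, X = X)
}

prep_covars <- function(covars, n, outlier_sd = 3) {
  if (is.null(covars)) return(NULL)
  covars <- as.matrix(tibble::as_tibble(covars))
  if (nrow(covars) != n) abort("Covariate rows must match outcome length.")
  # continuous covariates beyond 3 SD are set missing pre-fit
  for (j in seq_len(ncol(covars))) {
    v <- covars[, j]
    if (length(unique(stats::na.omit(v))) > 10) {
      z <- abs(v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
      covars[z > outlier_sd & !is.na(z), j] <- NA
    }
  }
  covars
}

#' Categorise the exposure into early / average / late
#'
#' The registered analyses also use a categorical pubertal-timing exposure.
#' Cut-points are configurable in SD units around the mean (default ±1 SD,
#' since the registered exact cut-offs are not published).
#'
#' @param x Exposure vector (years).
#' @param cutpoints Two increasing z-scale cut-points.
#' @return Factor with levels `early`, `average`, `late` (`NA` preserved).
#' @examples
#' table(categorize_exposure(rnorm(100, 12.69, 1.18)))
#' @export
categorize_exposure <- function(x, cutpoints = c(-1, 1)) {
  if (length(cutpoints) != 2 || diff(cutpoints) <= 0) {
    abort("`cutpoints` must be two increasing values.")
  }
  z <- (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
  cut(z, breaks = c(-Inf, cutpoints, Inf),
      labels = c("early", "average", "late"))
}

#' Linear regression of a continuous outcome on the exposure
#'
#' Ordinary (or inverse-probability weighted) least squares of a
#' standardised symptom outcome on the exposure, with optional covariate
#' adjustment. When weights are supplied the covariance is
#' heteroskedasticity-robust with the HC1 small-sample scaling
#' `n / (n - k)`; `robust = TRUE` forces the sandwich for unweighted fits
#' too. Continuous covariates further than 3 SD from their mean are set
#' missing before fitting. Rows with any missing value are dropped.
#'
#' @param y Continuous outcome (will typically already be transformed and
#'   standardised).
#' @param x Exposure.
#' @param covars Optional covariate data frame/matrix.
#' @param weights Optional positive case weights (IPW).
#' @param robust Force HC1 robust standard errors.
#' @param direction Registered direction for the one-tailed p-value.
#' @param scale_unit `exposure_unit` recorded in the estimate.
#' @param outcome Outcome label carried into the estimate row.
#' @param outlier_sd Continuous covariates beyond this many SDs from their
#'   mean are set missing before fitting (use `Inf` to disable).
#' @return An [new_estimate()] row for the exposure coefficient (beta
#'   scale), with attribute `fit` holding coefficients and covariance.
#' @examples
#' x <- rnorm(100); y <- -0.1 * x + rnorm(100)
#' fit_linear(y, x)$estimate
#' @export
fit_linear <- function(y, x, covars = NULL, weights = NULL, robust = FALSE,
                       direction = "negative", scale_unit = "per_year",
                       outcome = NA_character_, outlier_sd = 3) {
  covars <- prep_covars(covars, length(y), outlier_sd)
  X <- cbind(`(Intercept)` = 1, x = x, covars)
  ok <- complete.cases(X) & is.finite(y) &
    (if (is.null(weights)) TRUE else is.finite(weights))
  if (sum(ok) < ncol(X) + 2) abort("Too few complete rows to fit.")
  f <- ols_fit(y[ok], X[ok, , drop = FALSE],
               weights = if (is.null(weights)) NULL else weights[ok],
               robust = robust)
  i <- match("x", colnames(f$X))
  est <- new_estimate(f$beta[i], sqrt(f$vcov[i, i]), n = f$n,
                      scale = "beta", exposure_unit = scale_unit,
                      method = if (is.null(weights)) "linear"
                               else "linear+IPW",
                      outcome = outcome, direction = direction,
                      adjusted_for = colnames(covars) %||% character())
  attr(est, "fit") <- f[c("beta", "vcov", "n")]
  est
}

#' Logistic regression of a diagnosis on the exposure
#'
#' Maximum-likelihood logistic regression returning the log odds ratio per
#' unit of exposure, with an HC1-style robust (sandwich) covariance when
#' weights are supplied or `robust = TRUE`. Complete separation is detected
#' and raised as an error.
#'
#' @inheritParams fit_linear
#' @param case Binary (0/1 or logical) outcome; both classes must occur.
#' @return An [new_estimate()] row on the `log_or` scale.
#' @examples
#' x <- rnorm(500); case <- rbinom(500, 1, plogis(-2 + 0.3 * x))
#' fit_logistic(case, x)$scale
#' @export
fit_logistic <- function(case, x, covars = NULL, weights = NULL,
                         robust = FALSE, direction = "negative",
                         scale_unit = "per_year",
                         outcome = NA_character_, outlier_sd = 3) {
  case <- as.integer(case)
  covars <- prep_covars(covars, length(case), outlier_sd)
  dat <- data.frame(case = case, x = x)
  if (!is.null(covars)) dat <- cbind(dat, as.data.frame(covars))
  ok <- complete.cases(dat) &
    (if (is.null(weights)) TRUE else is.finite(weights))
  dat <- dat[ok, , drop = FALSE]
  if (length(unique(dat$case)) < 2) {
    abort("Both outcome classes must be present.")
  }
  w <- if (is.null(weights)) NULL else weights[ok]
  fit <- suppressWarnings(glm(case ~ ., family = binomial(), data = dat,
                              weights = w))
  p_hat <- fitted(fit)
  if (any(p_hat > 1 - 1e-8) || any(p_hat < 1e-8)) {
    abort("Separation detected in logistic model; cannot estimate log-OR.")
  }
  X <- model.matrix(fit)
  i <- match("x", colnames(X))
  if (robust || !is.null(weights)) {
    ww <- w %||% rep(1, nrow(X))
    score_res <- (dat$case - p_hat)         # glm score residuals
    info <- crossprod(X * sqrt(ww * p_hat * (1 - p_hat)))
    bread <- chol2inv(chol(info))
    meat <- crossprod(X * (ww * score_res))
    vc <- bread %*% meat %*% bread
    vc <- vc * nrow(X) / (nrow(X) - ncol(X))
  } else {
    vc <- suppressWarnings(stats::vcov(fit))
  }
  est <- new_estimate(coef(fit)[i], sqrt(vc[i, i]), n = nrow(dat),
                      scale = "log_or", exposure_unit = scale_unit,
                      method = if (is.null(weights)) "logistic"
                               else "logistic+IPW",
                      outcome = outcome, direction = direction,
                      adjusted_for = colnames(covars) %||% character())
  attr(est, "fit") <- list(beta = coef(fit), vcov = vc, n = nrow(dat))
  est
}
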