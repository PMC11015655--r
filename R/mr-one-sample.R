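#' Two-stage least squares (one-sample Mendelian randomisation)
#'
#' First regresses the exposure on the instrument(s) and takes the fitted
#' values ("genetically predicted" exposure); then regresses the outcome on
#' those fitted values. The reported covariance is the proper 2SLS one:
#' residuals are recomputed from the *original* exposure
#' (`e = y - [1, x] b`), not the first-stage fits, and a
#' heteroskedasticity-robust HC1 sandwich with `n / (n - k)` scaling is
#' applied. No covariates enter the MR model (adjusting an MR model can
#' itself introduce bias); the instrument should already be residualised on
#' batch and principal components.
#'
#' @param y Continuous outcome (standardised symptom score).
#' @param x Exposure (age at menarche, years).
#' @param instrument Vector or matrix of instruments (typically the
#'   residualised allele score).
#' @param robust Use HC1 robust covariance (default) instead of the
#'   homoskedastic 2SLS covariance.
#' @param direction Registered direction for the one-tailed p-value.
#' @param scale_unit Exposure unit recorded on the estimate.
#' @param outcome Outcome label.
#' @return An [new_estimate()] row (beta scale) with attribute
#'   `first_stage` carrying the first-stage R-squared and F statistic.
#' @examples
#' g <- rnorm(500); x <- 12.7 + 0.4 * g + rnorm(500)
#' y <- -0.06 * x + rnorm(500)
#' mr_tsls(y, x, g)$estimate
#' @export
mr_tsls <- function(y, x, instrument, robust = TRUE,
                    direction = "negative", scale_unit = "per_year",
                    outcome = NA_character_) {
  Z <- as.matrix(instrument)
  ok <- is.finite(y) & is.finite(x) & complete.cases(Z)
  y <- y[ok]; x <- x[ok]; Z <- Z[ok, , drop = FALSE]
  if (any(apply(Z, 2, sd) == 0)) abort("Instrument has zero variance.")
  n <- length(y)
  Z1 <- cbind(1, Z)
  fs <- lm.fit(Z1, x)
  xhat <- drop(Z1 %*% fs$coefficients)
  r2_fs <- 1 - sum(fs$residuals^2) / sum((x - mean(x))^2)
  k_fs <- ncol(Z)
  f_fs <- (r2_fs / k_fs) / ((1 - r2_fs) / (n - k_fs - 1))
  if (f_fs < 10) warn(sprintf("Weak instrument: first-stage F = %.2f.", f_fs))

  Xhat <- cbind(`(Intercept)` = 1, x = xhat)
  beta <- qr.coef(qr(Xhat), y)
  # 2SLS residuals use the observed exposure, not the fitted values
  res <- y - drop(cbind(1, x) %*% beta)
  if (robust) {
    vc <- hc1_vcov(Xhat, res)
  } else {
    sig2 <- sum(res^2) / (n - 2)
    vc <- chol2inv(chol(crossprod(Xhat))) * sig2
  }
  est <- new_estimate(beta[2], sqrt(vc[2, 2]), n = n, scale = "beta",
                      exposure_unit = scale_unit, method = "1SMR",
                      outcome = outcome, direction = direction)
  attr(est, "first_stage") <- list(r2 = r2_fs, f_stat = f_fs)
  est
}

#' Two-stage logistic MR for binary outcomes
#'
#' Two-stage predictor substitution: the binary diagnosis is regressed (by
#' maximum-likelihood logistic regression) on the first-stage fitted
#' exposure, giving a log odds ratio per unit of genetically predicted
#' exposure. Robust sandwich standard errors with HC1 scaling are reported.
#' Residual-inclusion (control-function) estimation is available behind
#' `residual_inclusion = TRUE`.
#'
#' @inheritParams mr_tsls
#' @param case Binary outcome vector.
#' @param residual_inclusion Add the first-stage residual as a control
#'   function instead of pure predictor substitution.
#' @return An [new_estimate()] row on the `log_or` scale.
#' @export
mr_tsls_logistic <- function(case, x, instrument, direction = "negative",
                             residual_inclusion = FALSE,
                             scale_unit = "per_year",
                             outcome = NA_character_) {
  Z <- as.matrix(instrument)
  case <- as.integer(case)
  ok <- !is.na(case) & is.finite(x) & complete.cases(Z)
  case <- case[ok]; x <- x[ok]; Z <- Z[ok, , drop = FALSE]
  if (length(unique(case)) < 2) abort("Both classes must be present.")
  if (any(apply(Z, 2, sd) == 0)) abort("Instrument has zero variance.")
  Z1 <- cbind(1, Z)
  fs <- lm.fit(Z1, x)
  xhat <- drop(Z1 %*% fs$coefficients)
  dat <- data.frame(case = case, x = xhat)
  if (residual_inclusion) dat$fs_resid <- fs$residuals
  fit <- suppressWarnings(glm(case ~ ., family = binomial(), data = dat))
  p_hat <- fitted(fit)
  if (any(p_hat > 1 - 1e-8) || any(p_hat < 1e-8)) {
    abort("Separation detected in second-stage logistic model.")
  }
  X <- model.matrix(fit)
  info <- crossprod(X * sqrt(p_hat * (1 - p_hat)))
  bread <- chol2inv(chol(info))
  meat <- crossprod(X * (case - p_hat))
  vc <- bread %*% meat %*% bread * nrow(X) / (nrow(X) - ncol(X))
  i <- match("x", colnames(X))
  r2_fs <- 1 - sum(fs$residuals^2) / sum((x - mean(x))^2)
  est <- new_estimate(coef(fit)[i], sqrt(vc[i, i]), n = length(case),
                      scale = "log_or", exposure_unit = scale_unit,
                      method = "1SMR-logistic", outcome = outcome,
                      direction = direction)
  attr(est, "first_stage") <- list(r2 = r2_fs)
  est
}

#' Negative-control outcome comparison
#'
#' A pre-pubertal outcome cannot be causally affected by pubertal timing, so
#' its MR "effect" estimates confounding. The main (age 14) estimate passes
#' the check when it is consistent with an effect *more extreme* than the
#' negative-control bound: with `L` the negative-control confidence bound
#' farthest from 0 in the registered direction, `z = (theta_main - L) /
#' se_main`, signed so that positive `z` means "less extreme than L", and
#' `p = 1 - Phi(z)`. The criterion is met (pass) when `p >= alpha`, i.e. we
#' fail to reject that the main effect is at least as extreme as `L`.
#'
#' @param est_main,est_negcontrol `aam_estimate` rows on the same scale.
#' @param alpha Test level.
#' @return Tibble with `z`, `p`, `bound` and logical `pass`.
#' @examples
#' main <- new_estimate(-0.07, 0.035, 100, "beta", "per_sd")
#' neg <- new_estimate(-0.03, 0.046, 100, "beta", "per_sd")
#' negative_control_test(main, neg)$pass
#' @export
negative_control_test <- function(est_main, est_negcontrol, alpha = 0.05) {
  assert_estimate(est_main, "est_main")
  assert_estimate(est_negcontrol, "est_negcontrol")
  if (est_main$scale != est_negcontrol$scale) {
    abort("Main and negative-control estimates must share a scale.")
  }
  dir <- est_main$direction
  if (dir == "two_sided") dir <- if (est_main$estimate < 0) "negative"
                                 else "positive"
  if (dir == "negative") {
    L <- est_negcontrol$ci_low
    z <- (est_main$estimate - L) / est_main$se
  } else {
    L <- est_negcontrol$ci_high
    z <- (L - est_main$estimate) / est_main$se
  }
  p <- 1 - pnorm(z)
  tibble::tibble(z = z, p = p, bound = L, pass = p >= alpha)
}

#' Rescale a per-SD estimate to a per-year estimate
#'
#' Standardised-exposure effects divide by the exposure SD to become
#' per-year effects: beta and SE are divided by `sd_exposure`; odds ratios
#' are raised to the power `1 / sd_exposure` (the log-OR divided). For
#' protective odds ratios the per-year *increase* in odds per year of
#' earlier exposure, `(1 / OR_per_year - 1) * 100`, is attached as attribute
#' `percent_increase_per_earlier_year`.
#'
#' @param est An `aam_estimate` with `exposure_unit == "per_sd"`.
#' @param sd_exposure Exposure standard deviation in years (> 0).
#' @return The rescaled `aam_estimate` (`exposure_unit == "per_year"`).
#' @examples
#' e <- new_estimate(log(0.74), 0.16, 9800, "log_or", "per_sd")
#' attr(rescale_per_year(e, 1.18), "percent_increase_per_earlier_year")
#' @export
rescale_per_year <- function(est, sd_exposure) {
  assert_estimate(est)
  if (!is.finite(sd_exposure) || sd_exposure <= 0) {
    abort("`sd_exposure` must be positive.")
  }
  if (est$exposure_unit == "per_year") {
    # inverse direction: convert back to per-SD
    out <- new_estimate(est$estimate * sd_exposure, est$se * sd_exposure,
                        n = est$n, scale = est$scale,
                        exposure_unit = "per_sd", method = est$method,
                        outcome = est$outcome, direction = est$direction,
                        level = est$level)
    return(out)
  }
  out <- new_estimate(est$estimate / sd_exposure, est$se / sd_exposure,
                      n = est$n, scale = est$scale,
                      exposure_unit = "per_year", method = est$method,
                      outcome = est$outcome, direction = est$direction,
                      level = est$level)
  if (est$scale == "log_or") {
    or_py <- exp(out$estimate)
    if (or_py < 1) {
      attr(out, "percent_increase_per_earlier_year") <- (1 / or_py - 1) * 100
    }
  }
  out
}

#' Absolute risk implied by a per-year odds ratio
#'
#' Translates a baseline risk and a per-year odds ratio into the absolute
#' risk after a one-year shift of the exposure: the baseline odds
#' `p / (1 - p)` are multiplied by the odds ratio and mapped back to a
#' probability.
#'
#' @param baseline_risk Probability in (0, 1).
#' @param or_per_year Odds ratio (> 0) for a one-year change in the
#'   direction of interest (use `1 / OR` for one year *earlier* when the OR
#'   is protective per later year).
#' @return Probability after the shift.
#' @examples
#' absolute_risk_shift(0.052, 1.2907)  # ~0.066
#' @export
absolute_risk_shift <- function(baseline_risk, or_per_year) {
  if (baseline_risk <= 0 || baseline_risk >= 1) {
    abort("`baseline_risk` must be in (0, 1).")
  }
  if (or_per_year <= 0) abort("`or_per_year` must be positive.")
  odds <- or_per_year * baseline_risk / (1 - baseline_risk)
  odds / (1 + odds)
}
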