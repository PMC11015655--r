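#' Truncated multiple imputation of the censored exposure
#'
#' Girls who had not yet reached menarche at interview have a right-censored
#' age at menarche. This imputes the censored values by drawing from a
#' normal linear regression of the observed exposure on predictors (by
#' default all symptom outcomes, diagnoses and covariates), truncated below
#' at `lower_bound` (default 15 years: an individual still pre-menarcheal at
#' ~14.4 cannot plausibly have a value below that). Parameter uncertainty is
#' propagated Bayesian-style per imputation (sigma^2 from its scaled
#' inverse-chi-square posterior, coefficients from their normal posterior),
#' and truncated draws use inverse-CDF sampling, so `m` completed datasets
#' are proper multiple imputations.
#'
#' @param cohort An `aam_cohort` tibble with `exposure_x`, `censored`.
#' @param m Number of completed datasets (>= 2).
#' @param predictors Character vector of predictor columns; defaults to all
#'   `sym_*`, `diag_*`, `neg_*` columns plus `edu`, `income`, `parity`,
#'   `mat_age`, `confounder_u`.
#' @param lower_bound Hard lower bound for imputed values, in years.
#' @param seed Seed controlling all draws.
#' @return A list of class `imputation_set`: `m`, `lower_bound`, and
#'   `completed`, a list of cohort copies with `exposure_x` filled. Observed
#'   values are never modified.
#' @examples
#' co <- sim_cohort(sim_params(n_individuals = 400, n_snps = 5, seed = 2))
#' imp <- impute_censored(co, m = 3, seed = 9)
#' min(imp$completed[[1]]$exposure_x[co$censored])
#' @export
impute_censored <- function(cohort, m = 20, predictors = NULL,
                            lower_bound = 15, seed = NULL) {
  if (m < 2) abort("`m` must be at least 2.")
  obs <- !cohort$censored
  if (!any(obs)) abort("No observed (uncensored) exposure values.")
  if (!any(cohort$censored)) {
    return(structure(list(m = m, lower_bound = lower_bound,
                          completed = replicate(m, cohort, simplify = FALSE)),
                     class = "imputation_set"))
  }
  if (is.null(predictors)) {
    predictors <- intersect(
      c(grep("^(sym|diag|neg)_", names(cohort), value = TRUE),
        c("edu", "income", "parity", "mat_age", "confounder_u")),
      names(cohort))
  }
  X <- cbind(1, as.matrix(cohort[predictors]))
  storage.mode(X) <- "double"
  y <- cohort$exposure_x
  qx <- qr(X[obs, , drop = FALSE])
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    X <- X[, keep, drop = FALSE]
    qx <- qr(X[obs, , drop = FALSE])
  }
  bhat <- qr.coef(qx, y[obs])
  res <- qr.resid(qx, y[obs])
  n_obs <- sum(obs); k <- ncol(X)
  df <- n_obs - k
  s2 <- sum(res^2) / df
  R <- qr.R(qx)
  XtXinv <- chol2inv(R)
  cens_idx <- which(cohort$censored)
  Xc <- X[cens_idx, , drop = FALSE]

  completed <- with_seed(seed, {
    purrr::map(seq_len(m), function(i) {
      sig2 <- df * s2 / rchisq(1, df)
      beta <- bhat + drop(chol(XtXinv * sig2) %*% rnorm(k))
      mu <- drop(Xc %*% beta)
      sig <- sqrt(sig2)
      plo <- pnorm(lower_bound, mu, sig)
      if (mean(plo) > 0.999) {
        warn(paste("Imputation model mean far below `lower_bound`:",
                   "nearly no mass above the truncation point."))
      }
      u <- runif(length(mu), plo, 1)
      draws <- qnorm(pmin(u, 1 - 1e-12), mu, sig)
      done <- cohort
      done$exposure_x[cens_idx] <- pmax(draws, lower_bound)
      done
    })
  })
  structure(list(m = m, lower_bound = lower_bound, completed = completed),
            class = "imputation_set")
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines `m` estimates of the same quantity from multiply imputed data:
#' the pooled point estimate is the mean; total variance is
#' `W + (1 + 1/m) B` with `W` the mean within-imputation variance and `B`
#' the between-imputation variance; degrees of freedom follow the classic
#' small-sample formula `(m - 1) (1 + W / ((1 + 1/m) B))^2`.
#'
#' @param estimates A list of `aam_estimate` rows (or a tibble of stacked
#'   estimates) on a common scale.
#' @return A pooled `aam_estimate` (normal-approximation CI and p-values,
#'   with attribute `df` carrying the Rubin degrees of freedom and
#'   `between_var`/`within_var` diagnostics).
#' @examples
#' e1 <- new_estimate(0.1, 0.1, 100, "beta", "per_sd")
#' e2 <- new_estimate(0.3, 0.1, 100, "beta", "per_sd")
#' pool_rubin(list(e1, e2))$se
#' @export
pool_rubin <- function(estimates) {
  if (is.data.frame(estimates)) {
    estimates <- split(estimates, seq_len(nrow(estimates)))
  }
  m <- length(estimates)
  if (m < 2) abort("Need at least 2 estimates to pool.")
  tab <- dplyr::bind_rows(lapply(estimates, tibble::as_tibble))
  if (dplyr::n_distinct(tab$scale) > 1) {
    abort("Cannot pool estimates on different scales (beta vs log_or).")
  }
  point <- mean(tab$estimate)
  W <- mean(tab$se^2)
  B <- if (m > 1) sum((tab$estimate - point)^2) / (m - 1) else 0
  total <- W + (1 + 1 / m) * B
  df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  col1 <- function(nm, default) {
    if (!is.null(tab[[nm]])) tab[[nm]][1] else default
  }
  out <- new_estimate(point, sqrt(total), n = max(tab$n),
                      scale = tab$scale[1],
                      exposure_unit = col1("exposure_unit", "per_year"),
                      method = paste0(col1("method", "pooled"), "+MI"),
                      outcome = col1("outcome", NA_character_),
                      direction = col1("direction", "negative"),
                      level = col1("level", 0.95))
  attr(out, "df") <- df
  attr(out, "within_var") <- W
  attr(out, "between_var") <- B
  out
}

#' Inverse-probability weights for selective attrition
#'
#' Fits a logistic model of study participation on baseline covariates and
#' returns stabilised weights `P(participation) / fitted_i` for the
#' participants, truncated at configurable percentiles. Under
#' missing-at-random attrition given those covariates, weighting the
#' participants recovers the invited-cohort distribution; the returned
#' balance table reports standardised participant/non-participant mean
#' differences before weighting and the weighted participant deviation from
#' the full-cohort mean after weighting.
#'
#' @param cohort Cohort tibble with a logical `participation` column.
#' @param covariates Character vector of baseline covariate columns used in
#'   the participation model (default `confounder_u`, `edu`, `income`).
#' @param truncate Percentile pair at which weights are truncated.
#' @return A list of class `weight_set`: `weights` (one per participant, in
#'   cohort order of participants), `model_coefs`, and `balance` (tibble of
#'   standardised differences unweighted vs weighted).
#' @export
ipw_weights <- function(cohort, covariates = c("confounder_u", "edu",
                                               "income"),
                        truncate = c(0.01, 0.99)) {
  covariates <- intersect(covariates, names(cohort))
  if (!length(covariates)) abort("No participation-model covariates found.")
  dat <- cohort[c("participation", covariates)]
  if (anyNA(dat)) abort("Participation and covariates must be complete.")
  f <- stats::as.formula(paste("participation ~",
                               paste(covariates, collapse = " + ")))
  fit <- glm(f, family = binomial(), data = dat)
  p_hat <- fitted(fit)
  if (any(p_hat <= 0)) abort("Fitted participation probability of 0.")
  marg <- mean(cohort$participation)
  w_all <- marg / p_hat
  part <- cohort$participation
  w <- w_all[part]
  qs <- quantile(w, truncate)
  w <- pmin(pmax(w, qs[1]), qs[2])

  # both columns compare participants with the full invited cohort, so the
  # weighted column is directly comparable with the unweighted one
  balance <- purrr::map_dfr(covariates, function(nm) {
    v <- cohort[[nm]]
    sdp <- sqrt((var(v[part]) + var(v)) / 2)
    tibble::tibble(
      covariate = nm,
      smd_unweighted = (mean(v[part]) - mean(v)) / sdp,
      smd_weighted = (weighted.mean(v[part], w) - mean(v)) / sdp
    )
  })
  structure(list(weights = w, model_coefs = coef(fit), balance = balance),
            class = "weight_set")
}
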