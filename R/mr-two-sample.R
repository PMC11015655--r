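# Summary-data (two-sample) MR estimators and pleiotropy diagnostics.

# Build an MR result row: an aam_estimate plus heterogeneity columns.
new_mr_result <- function(estimate, se, n_snps, method, q_stat = NA_real_,
                          q_df = NA_real_, direction = "negative",
                          level = 0.95, outcome = NA_character_) {
  out <- new_estimate(estimate, se, n = n_snps, scale = "beta",
                      exposure_unit = "per_year", method = method,
                      outcome = outcome, direction = direction,
                      level = level)
  out$q_stat <- q_stat
  out$q_df <- q_df
  out$q_p <- if (is.na(q_stat)) NA_real_ else {
    pchisq(q_stat, q_df, lower.tail = FALSE)
  }
  class(out) <- c("mr_result", class(out))
  out
}

#' Per-SNP Wald ratio estimates
#'
#' For each SNP the causal effect is estimated as the ratio of the
#' SNP-outcome to the SNP-exposure association, `ratio_j = beta_Y / beta_X`,
#' with the first-order standard error `se_Y / |beta_X|` (the second-order
#' delta-method term can be added with `second_order = TRUE`). SNPs with a
#' zero exposure association are dropped and logged.
#'
#' @param pair A `summary_pair` (aligned exposure/outcome summary tables).
#' @param second_order Add the second-order delta-method variance term
#'   `beta_Y^2 se_X^2 / beta_X^4`.
#' @return Tibble with `snp`, `ratio`, `se`, and the per-SNP inputs;
#'   attribute `dropped` lists zero-`beta_X` SNPs.
#' @examples
#' sp <- sim_summary_pair(sim_params(n_snps = 20, seed = 4))
#' head(wald_ratios(sp))
#' @export
wald_ratios <- function(pair, second_order = FALSE) {
  ex <- pair$exposure_stats; ou <- pair$outcome_stats
  check_aligned(ex, ou)
  zero <- ex$beta == 0
  if (any(zero)) {
    inform(paste0("Dropping SNPs with zero exposure beta: ",
                  paste(ex$snp[zero], collapse = ", ")))
  }
  ex <- ex[!zero, , drop = FALSE]; ou <- ou[!zero, , drop = FALSE]
  v <- ou$se^2 / ex$beta^2
  if (second_order) v <- v + ou$beta^2 * ex$se^2 / ex$beta^4
  out <- tibble::tibble(
    snp = ex$snp, ratio = ou$beta / ex$beta, se = sqrt(v),
    beta_x = ex$beta, se_x = ex$se, beta_y = ou$beta, se_y = ou$se
  )
  attr(out, "dropped") <- pair$exposure_stats$snp[zero]
  out
}

#' Inverse-variance weighted combination of Wald ratios
#'
#' The fixed-effect IVW estimate is the `1/se^2`-weighted mean of the
#' per-SNP Wald ratios. Heterogeneity is summarised by Cochran's Q with
#' `J - 1` degrees of freedom; when `Q/df > 1` and
#' `random_effects = TRUE` the standard error is inflated multiplicatively
#' by `sqrt(Q/df)` (multiplicative random-effects model).
#'
#' @param ratios Output of [wald_ratios()] (or any tibble with `ratio`,
#'   `se`).
#' @param random_effects Inflate the SE multiplicatively under
#'   overdispersion.
#' @param direction,level Passed to the estimate row.
#' @return A one-row `mr_result` tibble (method `"IVW"`) with `q_stat`,
#'   `q_df`, `q_p` columns and attribute `per_snp_q`.
#' @examples
#' r <- tibble::tibble(ratio = c(0.5, 0.3), se = c(0.1, 0.1))
#' mr_ivw(r)$estimate
#' @export
mr_ivw <- function(ratios, random_effects = TRUE, direction = "negative",
                   level = 0.95) {
  if (nrow(ratios) < 2) {
    abort("IVW needs at least 2 SNPs; use the Wald ratio directly.")
  }
  w <- 1 / ratios$se^2
  est <- sum(w * ratios$ratio) / sum(w)
  per_snp_q <- w * (ratios$ratio - est)^2
  q <- sum(per_snp_q)
  df <- nrow(ratios) - 1
  se <- sqrt(1 / sum(w))
  if (random_effects && df > 0 && q / df > 1) se <- se * sqrt(q / df)
  out <- new_mr_result(est, se, nrow(ratios), "IVW", q, df,
                       direction = direction, level = level)
  attr(out, "per_snp_q") <- per_snp_q
  out
}

#' MR-Egger regression
#'
#' Weighted regression of the outcome associations on the exposure
#' associations *with* an intercept, weights `1/se_Y^2`, after orienting all
#' exposure betas positive (flipping the outcome beta sign accordingly,
#' which leaves every estimator invariant). The slope estimates the causal
#' effect under the InSIDE assumption; the intercept estimates directional
#' pleiotropy (its distance from zero is the Egger pleiotropy test).
#' Standard errors use multiplicative random-effects scaling
#' `sqrt(max(1, Q/(J - 2)))`.
#'
#' @param pair A `summary_pair`.
#' @param direction,level Passed to the estimate row. The reporting level of
#'   the interval is per-method configurable.
#' @return A one-row `mr_result` (method `"MR-Egger"`) with attribute
#'   `egger_intercept`, itself an `aam_estimate`.
#' @export
mr_egger <- function(pair, direction = "negative", level = 0.95) {
  ex <- pair$exposure_stats; ou <- pair$outcome_stats
  check_aligned(ex, ou)
  J <- nrow(ex)
  if (J < 3) abort("MR-Egger needs at least 3 SNPs.")
  flip <- sign(ex$beta); flip[flip == 0] <- 1
  bx <- ex$beta * flip
  by <- ou$beta * flip
  w <- 1 / ou$se^2
  X <- cbind(intercept = 1, slope = bx)
  XtWX <- crossprod(X * sqrt(w))
  beta <- drop(solve(XtWX, crossprod(X * w, by)))
  res <- by - drop(X %*% beta)
  q <- sum(w * res^2)
  phi <- max(1, q / (J - 2))
  vc <- solve(XtWX) * phi
  out <- new_mr_result(beta[2], sqrt(vc[2, 2]), J, "MR-Egger",
                       q, J - 2, direction = direction, level = level)
  intercept <- new_estimate(beta[1], sqrt(vc[1, 1]), n = J, scale = "beta",
                            exposure_unit = "per_year",
                            method = "MR-Egger intercept",
                            direction = "two_sided", level = level)
  attr(out, "egger_intercept") <- intercept
  out
}

# weighted median of `x` with weights `w`, linear interpolation across the
# cumulative-weight 50% point (Bowden et al. convention).
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  if (cw[1] >= 0.5) return(x[1])
  if (cw[length(cw)] <= 0.5) return(x[length(x)])
  below <- max(which(cw < 0.5))
  x[below] + (x[below + 1] - x[below]) *
    (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}

#' Weighted median estimator
#'
#' The weighted median of the per-SNP Wald ratios with weights `1/se^2`;
#' consistent when SNPs contributing at least half of the total weight are
#' valid instruments. The standard error comes from a seeded parametric
#' bootstrap (ratios redrawn from `N(ratio_j, se_j^2)`).
#'
#' @param ratios Output of [wald_ratios()].
#' @param n_boot Bootstrap draws for the SE.
#' @param seed Seed for the bootstrap.
#' @param direction,level Passed to the estimate row.
#' @return A one-row `mr_result` (method `"Weighted median"`).
#' @export
mr_weighted_median <- function(ratios, n_boot = 1000, seed = NULL,
                               direction = "negative", level = 0.95) {
  if (nrow(ratios) < 3) abort("Weighted median needs at least 3 SNPs.")
  w <- 1 / ratios$se^2
  est <- weighted_median_point(ratios$ratio, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      r <- rnorm(nrow(ratios), ratios$ratio, ratios$se)
      weighted_median_point(r, w)
    }, double(1))
  })
  new_mr_result(est, sd(boots), nrow(ratios), "Weighted median",
                direction = direction, level = level)
}

#' Contamination-mixture estimator
#'
#' Profile likelihood over a grid of candidate causal effects: each SNP's
#' Wald ratio contributes the larger of a "valid" log-density
#' `N(theta, se_j^2)` and an "invalid" log-density `N(0, psi^2)`. The
#' estimate is the grid argmax; the confidence set is
#' `{theta : 2 (ll_max - ll(theta)) <= qchisq(level, 1)}` and the reported
#' interval is its range.
#'
#' @param ratios Output of [wald_ratios()].
#' @param psi Scale of the invalid component; default `1.5 * sd(ratio)`.
#' @param grid_n Number of grid points.
#' @param grid_range Range of candidate `theta` values; defaults to the
#'   ratio range expanded by 25%.
#' @param direction,level Passed to the estimate row.
#' @return A one-row `mr_result` (method `"Contamination mixture"`) with
#'   attributes `profile` (grid and log-likelihood) and `ci_set`.
#' @export
mr_conmix <- function(ratios, psi = NULL, grid_n = 2001, grid_range = NULL,
                      direction = "negative", level = 0.95) {
  if (nrow(ratios) < 3) {
    abort("Contamination mixture needs at least 3 SNPs.")
  }
  if (is.null(psi)) {
    psi <- 1.5 * sd(ratios$ratio)
    # degenerate spread (all ratios equal): any broad invalid component works
    if (!is.finite(psi) || psi <= 0) psi <- max(1, 2 * max(abs(ratios$ratio)))
  }
  if (!is.finite(psi) || psi <= 0) abort("`psi` must be positive.")
  if (is.null(grid_range)) {
    rng <- range(ratios$ratio)
    pad <- 0.25 * diff(rng) + 1e-8
    grid_range <- c(rng[1] - pad, rng[2] + pad)
  }
  if (diff(grid_range) <= 0 || grid_n < 10) abort("Degenerate theta grid.")
  # make sure the grid resolves the profile curvature (the valid-component
  # likelihood can be much narrower than the spread of the ratios)
  spacing <- 0.25 * sqrt(1 / sum(1 / ratios$se^2))
  grid_n <- max(grid_n, min(50001, ceiling(diff(grid_range) / spacing) + 1))
  grid <- seq(grid_range[1], grid_range[2], length.out = grid_n)
  invalid_ll <- dnorm(ratios$ratio, 0, psi, log = TRUE)
  ll <- vapply(grid, function(th) {
    sum(pmax(dnorm(ratios$ratio, th, ratios$se, log = TRUE), invalid_ll))
  }, double(1))
  imax <- which.max(ll)
  keep <- 2 * (ll[imax] - ll) <= stats::qchisq(level, 1)
  ci <- range(grid[keep])
  est <- grid[imax]
  se <- (ci[2] - ci[1]) / (2 * qnorm(1 - (1 - level) / 2))
  out <- new_mr_result(est, max(se, 1e-12), nrow(ratios),
                       "Contamination mixture", direction = direction,
                       level = level)
  # profile CI replaces the Wald interval
  out$ci_low <- ci[1]
  out$ci_high <- ci[2]
  attr(out, "profile") <- tibble::tibble(theta = grid, ll = ll)
  attr(out, "ci_set") <- grid[keep]
  out
}

# leave-one-out IVW slopes, vectorised: slope_(-j) for every j.
loo_ivw_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by); sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO global heterogeneity and outlier test
#'
#' The observed global statistic is the sum over SNPs of the
#' inverse-variance-weighted squared residual of each SNP from the
#' leave-that-SNP-out IVW fit. Its null distribution is simulated by
#' parametric resampling: outcome betas are redrawn about their
#' leave-one-out predictions with their reported standard errors, and the
#' statistic recomputed. The global p-value is the exceedance fraction;
#' per-SNP outlier p-values are computed analogously from each SNP's own
#' weighted squared residual and Bonferroni-flagged.
#'
#' @param pair A `summary_pair`.
#' @param n_sim Number of parametric resamples (warned below 100).
#' @param seed Seed for the resampling.
#' @param outlier_sig Familywise level for flagging outliers.
#' @return List of class `mr_presso` with `global_rss`, `global_p`,
#'   `per_snp` (tibble with residuals and outlier p-values) and `outliers`
#'   (flagged SNP ids).
#' @export
mr_presso <- function(pair, n_sim = 1000, seed = NULL, outlier_sig = 0.05) {
  ex <- pair$exposure_stats; ou <- pair$outcome_stats
  check_aligned(ex, ou)
  J <- nrow(ex)
  if (J < 4) abort("MR-PRESSO needs at least 4 SNPs.")
  if (n_sim < 100) warn("`n_sim` < 100 gives a very coarse p-value.")
  bx <- ex$beta; by <- ou$beta; w <- 1 / ou$se^2
  slopes <- loo_ivw_slopes(bx, by, w)
  res_obs <- by - slopes * bx
  per_obs <- w * res_obs^2
  rss_obs <- sum(per_obs)
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      by_s <- rnorm(J, slopes * bx, ou$se)
      sl_s <- loo_ivw_slopes(bx, by_s, w)
      r <- by_s - sl_s * bx
      w * r^2
    }, double(J))
  })
  sims <- matrix(sims, nrow = J)
  rss_sim <- colSums(sims)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  p_snp <- (1 + rowSums(sims >= per_obs)) / (n_sim + 1)
  flagged <- ex$snp[p_snp * J < outlier_sig]
  structure(list(
    global_rss = rss_obs, global_p = global_p,
    per_snp = tibble::tibble(snp = ex$snp, residual = res_obs,
                             weighted_sq_residual = per_obs,
                             outlier_p = p_snp,
                             flagged = p_snp * J < outlier_sig),
    outliers = flagged, n_sim = n_sim
  ), class = "mr_presso")
}

#' Multivariable MR with conditional instrument strength
#'
#' Regresses the outcome associations on several exposures' association
#' columns jointly (no intercept, weights `1/se_Y^2`), estimating the
#' *direct* effect of each exposure. Reports, per exposure, the conditional
#' F statistic — the heterogeneity statistic of regressing that exposure's
#' betas on the other exposures' betas (weighted by the inverse variance of
#' its own betas) divided by `J - K` — and the modified Q statistic for
#' residual heterogeneity with `J - K` degrees of freedom. Assumes
#' non-overlapping exposure GWAS samples (zero covariance between exposure
#' estimates).
#'
#' @param exposures Named list of exposure summary tibbles (each with
#'   `snp`, `beta`, `se`), all aligned to the same SNPs and alleles.
#' @param outcome_stats Outcome summary tibble aligned to the same SNPs.
#' @param direction,level Passed to the estimate rows.
#' @return An `mr_result` tibble with one row per exposure (method
#'   `"MVMR"`), columns `conditional_f`, and attributes `modified_q`
#'   (statistic, df, p).
#' @export
mr_mvmr <- function(exposures, outcome_stats, direction = "negative",
                    level = 0.95) {
  if (!is.list(exposures) || is.data.frame(exposures)) {
    abort("`exposures` must be a named list of summary tibbles.")
  }
  K <- length(exposures)
  nm <- names(exposures) %||% paste0("exposure", seq_len(K))
  for (ex in exposures) check_aligned(ex, outcome_stats)
  J <- nrow(outcome_stats)
  if (J <= K + 1) abort("Need more SNPs than exposures plus one.")
  BX <- vapply(exposures, function(e) e$beta, double(J))
  SX <- vapply(exposures, function(e) e$se, double(J))
  if (qr(BX)$rank < K) abort("Collinear exposure association columns.")
  by <- outcome_stats$beta
  w <- 1 / outcome_stats$se^2
  XtWX <- crossprod(BX * sqrt(w))
  beta <- drop(solve(XtWX, crossprod(BX * w, by)))
  res <- by - drop(BX %*% beta)
  q_mod <- sum(w * res^2)
  phi <- max(1, q_mod / (J - K))
  vc <- solve(XtWX) * phi

  cond_f <- vapply(seq_len(K), function(k) {
    wk <- 1 / SX[, k]^2
    others <- BX[, -k, drop = FALSE]
    if (ncol(others) == 0) {
      fit_res <- BX[, k] - weighted.mean(BX[, k], wk)
    } else {
      Xo <- cbind(1, others)
      bo <- drop(solve(crossprod(Xo * sqrt(wk)),
                       crossprod(Xo * wk, BX[, k])))
      fit_res <- BX[, k] - drop(Xo %*% bo)
    }
    sum(wk * fit_res^2) / (J - K)
  }, double(1))

  rows <- purrr::map(seq_len(K), function(k) {
    r <- new_mr_result(beta[k], sqrt(vc[k, k]), J, "MVMR",
                       q_mod, J - K, direction = direction, level = level)
    r$exposure <- nm[k]
    r$conditional_f <- cond_f[k]
    r
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mr_result", class(out))
  attr(out, "modified_q") <- list(
    statistic = q_mod, df = J - K,
    p = pchisq(q_mod, J - K, lower.tail = FALSE))
  out
}

#' Run the full two-sample sensitivity battery
#'
#' Convenience wrapper running IVW, MR-Egger, weighted median, contamination
#' mixture and MR-PRESSO on one summary pair, returning a tidy table with
#' one row per method (the machine-readable twin of a forest-plot panel).
#'
#' @param pair A `summary_pair`.
#' @param seed Seed shared by the stochastic components (weighted-median
#'   bootstrap, PRESSO resampling).
#' @param n_sim PRESSO resamples; `n_boot` weighted-median bootstrap draws.
#' @param n_boot Bootstrap draws for the weighted median.
#' @param direction Registered direction for one-tailed p-values.
#' @param egger_level Reporting level for the MR-Egger interval (per-method
#'   configurable; some reports print 90% for Egger).
#' @return Tibble with one row per method; attributes `presso` and
#'   `egger_intercept` keep the full diagnostic objects.
#' @export
mr_battery <- function(pair, seed = NULL, n_sim = 1000, n_boot = 1000,
                       direction = "negative", egger_level = 0.95) {
  ratios <- wald_ratios(pair)
  ivw <- mr_ivw(ratios, direction = direction)
  egger <- mr_egger(pair, direction = direction, level = egger_level)
  wm <- mr_weighted_median(ratios, n_boot = n_boot,
                           seed = child_seed(seed, 1L),
                           direction = direction)
  cm <- mr_conmix(ratios, direction = direction)
  pr <- mr_presso(pair, n_sim = n_sim, seed = child_seed(seed, 2L))
  out <- dplyr::bind_rows(tidy(ivw), tidy(egger), tidy(wm), tidy(cm))
  out$n_snps <- out$n
  attr(out, "presso") <- pr
  attr(out, "egger_intercept") <- attr(egger, "egger_intercept")
  out
}
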