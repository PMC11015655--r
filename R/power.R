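# Monte-Carlo power for every registered test family.

power_result <- function(family, n, d, reps, alpha, tails, power,
                         prevalence = NA_real_, r2_instrument = NA_real_,
                         convention = NA_character_, seed = NA_integer_) {
  tibble::tibble(
    family = family, n = as.integer(n), d = d,
    prevalence = prevalence, r2_instrument = r2_instrument,
    tails = as.integer(tails), alpha = alpha, reps = as.integer(reps),
    convention = convention, power = power,
    mc_se = sqrt(power * (1 - power) / reps),
    seed = as.integer(seed %||% NA_integer_)
  )
}

# one-/two-tailed rejection from a z statistic, direction = sign of d
# (negative direction when d == 0, matching the registered hypotheses).
reject_z <- function(z, d, alpha, tails) {
  if (tails == 2) return(abs(z) > qnorm(1 - alpha / 2))
  if (d > 0) z > qnorm(1 - alpha) else z < qnorm(alpha)
}

#' Monte-Carlo power of the linear-regression test
#'
#' Simulates, `reps` times, an exposure distributed as age at menarche
#' (Normal(12.69, 1.18^2)) and a continuous symptom outcome with mean 5.71
#' and SD 4.93 whose association is set by converting Cohen's D to a
#' correlation `r = d / sqrt(d^2 + 4)`; fits the simple linear regression
#' and counts rejections of the (one-tailed by default) test at `alpha`.
#'
#' @param n Sample size per replicate.
#' @param d Cohen's D of the simulated association (sign gives the tested
#'   direction; `d = 0` estimates the type-I error rate).
#' @param reps Number of simulation replicates.
#' @param alpha Test level.
#' @param tails 1 (registered, directional) or 2.
#' @param seed Seed for the whole grid of replicates.
#' @param exposure_mean,exposure_sd,outcome_mean,outcome_sd Scale of the
#'   simulated variables (defaults match the registered simulation).
#' @return A one-row power tibble: `family`, `n`, `d`, `tails`, `alpha`,
#'   `reps`, `power`, `mc_se`.
#' @examples
#' power_linear(500, 0.3, reps = 200, seed = 1)$power
#' @export
power_linear <- function(n, d, reps = 1000, alpha = 0.05, tails = 1,
                         seed = NULL, exposure_mean = 12.69,
                         exposure_sd = 1.18, outcome_mean = 5.71,
                         outcome_sd = 4.93) {
  if (n < 10) abort("`n` must be at least 10.")
  r <- d / sqrt(d^2 + 4)
  rej <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      zx <- rnorm(n)
      y <- outcome_mean +
        outcome_sd * (r * zx + sqrt(1 - r^2) * rnorm(n))
      x <- exposure_mean + exposure_sd * zx
      r_hat <- cor(x, y)
      # slope test in simple regression == correlation test
      z <- r_hat * sqrt((n - 2) / (1 - r_hat^2))
      reject_z(z, d, alpha, tails)
    }, logical(1))
  })
  power_result("linear", n, d, reps, alpha, tails, mean(rej), seed = seed)
}

# intercept for target marginal prevalence with standard-normal exposure
logistic_intercept <- function(b, prevalence) {
  gh <- seq(-6, 6, length.out = 401)
  wgh <- dnorm(gh); wgh <- wgh / sum(wgh)
  uniroot(function(b0) sum(wgh * plogis(b0 + b * gh)) - prevalence,
          c(-30, 30), tol = 1e-10)$root
}

#' Monte-Carlo power of the logistic-regression test
#'
#' Simulates a standardised exposure and a binary outcome from a logistic
#' model whose intercept is tuned numerically to the target prevalence and
#' whose per-SD log odds ratio is `d * pi / sqrt(3)`; fits the logistic
#' regression and counts Wald-test rejections.
#'
#' @inheritParams power_linear
#' @param prevalence Marginal outcome prevalence in (0, 1).
#' @return A one-row power tibble.
#' @examples
#' power_logistic(800, 0.4, prevalence = 0.2, reps = 100, seed = 1)$power
#' @export
power_logistic <- function(n, d, prevalence, reps = 1000, alpha = 0.05,
                           tails = 1, seed = NULL) {
  if (prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must be in (0, 1).")
  }
  if (n * prevalence < 10) {
    warn("Fewer than 10 expected cases per replicate.")
  }
  b <- d * pi / sqrt(3)
  b0 <- logistic_intercept(b, prevalence)
  rej <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      x <- rnorm(n)
      case <- rbinom(n, 1L, plogis(b0 + b * x))
      if (sum(case) < 2 || sum(case) > n - 2) return(FALSE)
      fit <- suppressWarnings(
        glm.fit(cbind(1, x), case, family = binomial()))
      p_hat <- fit$fitted.values
      X <- cbind(1, x)
      vc <- chol2inv(chol(crossprod(X * sqrt(p_hat * (1 - p_hat)))))
      z <- fit$coefficients[2] / sqrt(vc[2, 2])
      reject_z(z, d, alpha, tails)
    }, logical(1))
  })
  power_result("logistic", n, d, reps, alpha, tails, mean(rej),
               prevalence = prevalence, seed = seed)
}

#' Monte-Carlo power of the 2SLS (one-sample MR) test
#'
#' Simulates a genetic instrument explaining `r2_instrument` of the
#' exposure variance and a causal effect of size `d`, fits two-stage least
#' squares (or the two-stage logistic model when `binary = TRUE`) and
#' counts rejections. Because the registered mapping from Cohen's D to the
#' simulated causal association is ambiguous, both conventions are
#' available: `"per_sd"` sizes the effect as `d / sqrt(d^2 + 4)` SD of
#' outcome per SD of exposure; `"per_year"` applies the same coefficient
#' per year of exposure. `convention = "both"` emits one row per reading.
#'
#' @inheritParams power_logistic
#' @param r2_instrument Variance in the exposure explained by the
#'   instrument, in (0, 1).
#' @param binary Use a logistic second stage with prevalence `prevalence`.
#' @param convention `"per_sd"`, `"per_year"` or `"both"`.
#' @param exposure_sd Exposure SD in years.
#' @return A power tibble with one row per convention.
#' @examples
#' power_tsls(2000, 0.3, r2_instrument = 0.1, reps = 100, seed = 1)
#' @export
power_tsls <- function(n, d, r2_instrument, reps = 1000, alpha = 0.05,
                       tails = 1, binary = FALSE, prevalence = NULL,
                       seed = NULL, convention = "per_sd",
                       exposure_sd = 1.18) {
  if (r2_instrument <= 0 || r2_instrument >= 1) {
    abort("`r2_instrument` must be in (0, 1).")
  }
  if (n * r2_instrument < 30) {
    warn("Effective first-stage information n * r2 < 30; power unreliable.")
  }
  if (binary && is.null(prevalence)) {
    abort("`prevalence` required when `binary = TRUE`.")
  }
  conventions <- if (convention == "both") c("per_sd", "per_year") else {
    convention
  }
  base_beta <- d / sqrt(d^2 + 4)   # SD outcome per SD exposure
  b_logit <- d * pi / sqrt(3)
  out <- purrr::map_dfr(seq_along(conventions), function(ci) {
    conv <- conventions[ci]
    # effect per *year*; under "per_sd" convert using the exposure SD
    beta_year <- if (conv == "per_sd") base_beta / exposure_sd else base_beta
    b_logit_year <- if (conv == "per_sd") b_logit / exposure_sd else b_logit
    rej <- with_seed(child_seed(seed, ci), {
      vapply(seq_len(reps), function(i) {
        g <- rnorm(n)
        x_std <- sqrt(r2_instrument) * g +
          sqrt(1 - r2_instrument) * rnorm(n)
        x <- 12.69 + exposure_sd * x_std
        xc <- x - mean(x)
        gc <- g - mean(g)
        if (!binary) {
          y <- beta_year * xc + rnorm(n)
          b2 <- sum(gc * y) / sum(gc * xc)      # single-instrument 2SLS
          xhat_c <- gc * sum(gc * xc) / sum(gc^2)
          res <- y - mean(y) - b2 * xc
          Xh <- cbind(1, xhat_c)
          vc <- hc1_vcov(Xh, res)
          z <- b2 / sqrt(vc[2, 2])
        } else {
          lp <- b_logit_year * xc
          b0 <- solve_intercept(lp, prevalence)
          case <- rbinom(n, 1L, plogis(b0 + lp))
          if (sum(case) < 2 || sum(case) > n - 2) return(FALSE)
          xhat <- mean(x) + gc * sum(gc * xc) / sum(gc^2)
          fit <- suppressWarnings(
            glm.fit(cbind(1, xhat), case, family = binomial()))
          p_hat <- fit$fitted.values
          X <- cbind(1, xhat)
          info <- crossprod(X * sqrt(p_hat * (1 - p_hat)))
          bread <- chol2inv(chol(info))
          meat <- crossprod(X * (case - p_hat))
          vc <- bread %*% meat %*% bread
          z <- fit$coefficients[2] / sqrt(vc[2, 2])
        }
        reject_z(z, d, alpha, tails)
      }, logical(1))
    })
    power_result(if (binary) "tsls_logistic" else "tsls", n, d, reps,
                 alpha, tails, mean(rej),
                 prevalence = prevalence %||% NA_real_,
                 r2_instrument = r2_instrument, convention = conv,
                 seed = seed)
  })
  out
}

#' Run a grid of power scenarios
#'
#' Expands a scenario grid and evaluates the matching power function for
#' each row, returning a long results table suitable for plotting power
#' curves.
#'
#' @param grid A data frame with columns `family` (`"linear"`,
#'   `"logistic"`, `"tsls"`, `"tsls_logistic"`), `n`, `d` and optionally
#'   `prevalence`, `r2_instrument`, `tails`.
#' @param reps Replicates per scenario.
#' @param alpha Test level.
#' @param seed Base seed; each scenario uses a derived child seed.
#' @return Long tibble of power results, one row per scenario.
#' @export
power_grid <- function(grid, reps = 1000, alpha = 0.05, seed = 1) {
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    s <- child_seed(seed, i)
    tails <- if ("tails" %in% names(g)) g$tails else 1
    switch(as.character(g$family),
      linear = power_linear(g$n, g$d, reps, alpha, tails, seed = s),
      logistic = power_logistic(g$n, g$d, g$prevalence, reps, alpha,
                                tails, seed = s),
      tsls = power_tsls(g$n, g$d, g$r2_instrument, reps, alpha, tails,
                        seed = s),
      tsls_logistic = power_tsls(g$n, g$d, g$r2_instrument, reps, alpha,
                                 tails, binary = TRUE,
                                 prevalence = g$prevalence, seed = s),
      abort(sprintf("Unknown power family '%s'.", g$family))
    )
  })
}
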