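#' Registered hypothesis specifications
#'
#' One row per pre-registered hypothesis: its id, outcome domain, analysis
#' family, registered direction, smallest effect size of interest (SESOI, as
#' a Cohen's D), the scale the estimate lives on, and whether a
#' negative-control criterion applies. The SESOIs follow the registered
#' design: D = 0.23 for observational depression tests, 0.25 for MR
#' depression tests, 0.22 for observational tests in other domains and 0.20
#' for MR tests in other domains. Depression hypotheses are one-tailed
#' (negative registered direction); other domains are two-sided.
#'
#' @return A tibble with columns `id`, `domain`, `outcome_type`, `family`,
#'   `direction`, `sesoi_d`, `scale`, `requires_negcontrol`, `alpha`.
#' @examples
#' hypothesis_specs()
#' @export
hypothesis_specs <- function() {
  tribble_ <- tibble::tribble
  tribble_(
    ~id,      ~domain,      ~outcome_type, ~family,        ~direction,  ~sesoi_d, ~scale,   ~requires_negcontrol,
    "H1a",    "depression", "symptom",     "observational", "negative",  0.23,     "beta",   FALSE,
    "H1b",    "depression", "diagnosis",   "observational", "negative",  0.23,     "log_or", FALSE,
    "H2.1a",  "anxiety",    "symptom",     "observational", "two_sided", 0.22,     "beta",   FALSE,
    "H2.2a",  "cd",         "symptom",     "observational", "two_sided", 0.22,     "beta",   FALSE,
    "H2.3a",  "odd",        "symptom",     "observational", "two_sided", 0.22,     "beta",   FALSE,
    "H2.4a",  "adhd",       "symptom",     "observational", "two_sided", 0.22,     "beta",   FALSE,
    "H2.1b",  "anxiety",    "diagnosis",   "observational", "two_sided", 0.22,     "log_or", FALSE,
    "H2.2b",  "dbd",        "diagnosis",   "observational", "two_sided", 0.22,     "log_or", FALSE,
    "H2.3b",  "adhd",       "diagnosis",   "observational", "two_sided", 0.22,     "log_or", FALSE,
    "H3a",    "depression", "symptom",     "mr",            "negative",  0.25,     "beta",   TRUE,
    "H3b",    "depression", "diagnosis",   "mr",            "negative",  0.25,     "log_or", FALSE,
    "H4.1a",  "anxiety",    "symptom",     "mr",            "two_sided", 0.20,     "beta",   TRUE,
    "H4.2a",  "cd",         "symptom",     "mr",            "two_sided", 0.20,     "beta",   TRUE,
    "H4.3a",  "odd",        "symptom",     "mr",            "two_sided", 0.20,     "beta",   TRUE,
    "H4.4a",  "adhd",       "symptom",     "mr",            "two_sided", 0.20,     "beta",   TRUE,
    "H4.1b",  "anxiety",    "diagnosis",   "mr",            "two_sided", 0.20,     "log_or", FALSE,
    "H4.2b",  "dbd",        "diagnosis",   "mr",            "two_sided", 0.20,     "log_or", FALSE,
    "H4.3b",  "adhd",       "diagnosis",   "mr",            "two_sided", 0.20,     "log_or", FALSE
  ) |>
    dplyr::mutate(alpha = 0.05)
}

#' Convert a Cohen's D SESOI to an analysis scale
#'
#' The registered smallest effect size of interest is expressed as a
#' Cohen's D; estimates live on a standardised-beta or log odds ratio
#' scale. For the beta scale (standardised outcome, per-SD exposure) the
#' point-biserial-style conversion `bound = d / sqrt(d^2 + 4)` is used; for
#' the log-OR scale the logistic conversion `bound = d * pi / sqrt(3)`.
#'
#' @param d Cohen's D (>= 0).
#' @param scale `"beta"` or `"log_or"`.
#' @return The (positive) equivalence bound on the requested scale.
#' @examples
#' sesoi_to_scale(0.23, "beta")    # 0.1142
#' sesoi_to_scale(0.25, "log_or")  # 0.4535
#' @export
sesoi_to_scale <- function(d, scale = c("beta", "log_or")) {
  scale <- match.arg(scale)
  if (d < 0 || !is.finite(d)) abort("`d` must be a non-negative number.")
  switch(scale,
         beta = d / sqrt(d^2 + 4),
         log_or = d * pi / sqrt(3))
}

#' One-sided inferiority test against the SESOI
#'
#' Tests `H0: the population effect is at least as extreme as the bound in
#' the registered direction`. For a negative-direction hypothesis the test
#' statistic is `z = (theta_hat - (-bound)) / se` and `p = 1 - Phi(z)`;
#' rejecting means the effect is demonstrably *less* extreme than the
#' smallest effect size of interest (practically inside the region of
#' equivalence on that side).
#'
#' @param est An `aam_estimate` row.
#' @param bound Positive SESOI bound on the estimate's scale.
#' @param direction `"negative"` or `"positive"` registered direction
#'   (defaults to the estimate's own direction).
#' @param alpha Test level.
#' @return Tibble with `z`, `p` and logical `reject`.
#' @export
inferiority_test <- function(est, bound, direction = NULL, alpha = 0.05) {
  assert_estimate(est)
  if (bound < 0) abort("`bound` must be non-negative.")
  direction <- direction %||% est$direction
  if (direction == "two_sided") {
    abort("Use `equivalence_test()` for two-sided hypotheses.")
  }
  z <- if (direction == "negative") {
    (est$estimate - (-bound)) / est$se
  } else {
    (bound - est$estimate) / est$se
  }
  p <- 1 - pnorm(z)
  tibble::tibble(z = z, p = p, reject = p < alpha)
}

#' Two one-sided tests (TOST) of equivalence
#'
#' Tests whether the effect is demonstrably inside `(-bound, bound)`: two
#' one-sided tests against the bounds, with the reported p the larger of
#' the two. Rejection declares the effect practically equivalent to 0.
#'
#' @inheritParams inferiority_test
#' @return Tibble with `p_lower`, `p_upper`, `p` (max) and `reject`.
#' @export
equivalence_test <- function(est, bound, alpha = 0.05) {
  assert_estimate(est)
  if (bound < 0) abort("`bound` must be non-negative.")
  p_upper <- 1 - pnorm((bound - est$estimate) / est$se)
  p_lower <- 1 - pnorm((est$estimate - (-bound)) / est$se)
  p <- pmax(p_lower, p_upper)
  tibble::tibble(p_lower = p_lower, p_upper = p_upper, p = p,
                 reject = p < alpha)
}

#' The registered decision engine
#'
#' Combines the null-hypothesis significance test, the
#' inferiority/equivalence test against the SESOI and (where required) the
#' negative-control criterion into the registered verdict:
#'
#' * `practically_equivalent_to_0` if the inferiority/equivalence test
#'   rejects — irrespective of the NHST;
#' * otherwise `supported` if the NHST rejects 0 in the registered
#'   direction *and* the negative-control criterion (when required) passes;
#' * otherwise `undecided`.
#'
#' @param spec One row of [hypothesis_specs()] (or a compatible list with
#'   `id`, `direction`, `sesoi_d`, `scale`, `requires_negcontrol`,
#'   `alpha`).
#' @param est The `aam_estimate` for the hypothesis, on the scale named in
#'   the hypothesis row (per-SD exposure units).
#' @param negcontrol_result Result of [negative_control_test()], required
#'   when the hypothesis row demands it.
#' @return A one-row tibble: `id`, `verdict`, `nhst_p`, `equivalence_p`,
#'   `negcontrol_pass`, `bound`, plus the estimate columns.
#' @examples
#' spec <- hypothesis_specs()[1, ]
#' est <- new_estimate(-0.11, 0.008, 13000, "beta", "per_sd")
#' decide_hypothesis(spec, est)$verdict
#' @export
decide_hypothesis <- function(spec, est, negcontrol_result = NULL) {
  assert_estimate(est)
  if (isTRUE(spec$requires_negcontrol) && is.null(negcontrol_result)) {
    abort(sprintf("Hypothesis %s requires a negative-control result.",
                  spec$id))
  }
  if (est$scale != spec$scale) {
    abort(sprintf("Estimate scale '%s' does not match spec scale '%s'.",
                  est$scale, spec$scale))
  }
  alpha <- spec$alpha %||% 0.05
  bound <- sesoi_to_scale(spec$sesoi_d, spec$scale)
  z <- est$estimate / est$se
  if (spec$direction == "two_sided") {
    nhst_p <- 2 * pnorm(-abs(z))
    eq <- equivalence_test(est, bound, alpha = alpha)
  } else {
    nhst_p <- if (spec$direction == "negative") pnorm(z) else {
      pnorm(z, lower.tail = FALSE)
    }
    eq <- inferiority_test(est, bound, direction = spec$direction,
                           alpha = alpha)
  }
  nc_pass <- if (isTRUE(spec$requires_negcontrol)) {
    isTRUE(negcontrol_result$pass)
  } else NA
  verdict <- if (eq$reject) {
    "practically_equivalent_to_0"
  } else if (nhst_p < alpha && (is.na(nc_pass) || nc_pass)) {
    "supported"
  } else {
    "undecided"
  }
  tibble::tibble(
    id = spec$id, verdict = verdict, nhst_p = nhst_p,
    equivalence_p = eq$p, negcontrol_pass = nc_pass, bound = bound,
    estimate = est$estimate, se = est$se, ci_low = est$ci_low,
    ci_high = est$ci_high, scale = est$scale, method = est$method,
    n = est$n
  )
}
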