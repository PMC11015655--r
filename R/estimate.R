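#' Effect estimates as tidy one-row tibbles
#'
#' Every model-fitting verb in menarchemr returns an `aam_estimate`: a one-row
#' tibble carrying the point estimate, its standard error, a Wald confidence
#' interval, one- and two-tailed p-values and scale metadata. Keeping the
#' container tabular means estimates pipe straight into `dplyr::bind_rows()`
#' to build results tables mirroring forest-plot panels.
#'
#' The `scale` field distinguishes linear coefficients (`"beta"`, standardised
#' outcome units per unit exposure) from logistic ones (`"log_or"`). The
#' `exposure_unit` field records whether the exposure was entered per year of
#' age at menarche or per standard deviation; [rescale_per_year()] converts
#' between the two. One-tailed p-values are computed against the registered
#' direction of each hypothesis (`"negative"` for the depression hypotheses):
#' for a negative registered direction `p_one = Phi(z)`, small when the
#' estimate is convincingly below zero.
#'
#' @param estimate Point estimate (beta or log odds ratio).
#' @param se Standard error, positive.
#' @param n Number of observations (or SNPs, for summary-data estimators).
#' @param scale `"beta"` or `"log_or"`.
#' @param exposure_unit `"per_year"`, `"per_sd"` or `"raw"`.
#' @param method Label for the estimator that produced the value.
#' @param outcome Optional outcome label.
#' @param direction Registered direction of the hypothesis: `"negative"`,
#'   `"positive"` or `"two_sided"` (then `p_one` is the smaller tail).
#' @param adjusted_for Character vector of covariate names (collapsed into a
#'   single string in the output).
#' @param level Confidence level for the interval, default 0.95.
#'
#' @return A one-row tibble of class `aam_estimate` with columns `method`,
#'   `outcome`, `scale`, `exposure_unit`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p_one`, `p_two`, `n`, `direction`, `adjusted_for`, `level`.
#' @examples
#' new_estimate(-0.07, 0.033, n = 9832, scale = "beta",
#'              exposure_unit = "per_sd", method = "1SMR")
#' @export
new_estimate <- function(estimate, se, n,
                         scale = c("beta", "log_or"),
                         exposure_unit = c("per_sd", "per_year", "raw"),
                         method = "custom",
                         outcome = NA_character_,
                         direction = c("negative", "positive", "two_sided"),
                         adjusted_for = character(),
                         level = 0.95) {
  scale <- match.arg(scale)
  exposure_unit <- match.arg(exposure_unit)
  direction <- match.arg(direction)
  estimate <- unname(estimate)
  se <- unname(se)
  if (!is.finite(estimate)) abort("`estimate` must be finite.")
  if (!is.finite(se) || se <= 0) abort("`se` must be a positive number.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  z <- estimate / se
  zc <- qnorm(1 - (1 - level) / 2)
  p_one <- switch(direction,
    negative  = pnorm(z),
    positive  = pnorm(z, lower.tail = FALSE),
    two_sided = pmin(pnorm(z), pnorm(z, lower.tail = FALSE))
  )
  out <- tibble::tibble(
    method = method,
    outcome = outcome,
    scale = scale,
    exposure_unit = exposure_unit,
    estimate = estimate,
    se = se,
    ci_low = estimate - zc * se,
    ci_high = estimate + zc * se,
    p_one = p_one,
    p_two = 2 * pmin(pnorm(z), pnorm(z, lower.tail = FALSE)),
    n = as.integer(n),
    direction = direction,
    adjusted_for = paste(adjusted_for, collapse = ","),
    level = level
  )
  class(out) <- c("aam_estimate", class(out))
  out
}

is_estimate <- function(x) inherits(x, "aam_estimate")

assert_estimate <- function(x, arg = "est") {
  if (!is_estimate(x)) abort(sprintf("`%s` must be an `aam_estimate`.", arg))
  invisible(x)
}

#' @export
tidy.aam_estimate <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), c("aam_estimate", "mr_result"))
  out
}

#' @export
glance.aam_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, estimate = x$estimate, se = x$se,
                 p_two = x$p_two, n = x$n)
}

#' Broom-style tidiers
#'
#' `tidy()` returns the estimate table as a plain tibble; `glance()` returns a
#' one-row summary. Registered as S3 generics here since broom is not a
#' dependency.
#' @param x Object to tidy.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
print.aam_estimate <- function(x, ...) {
  cat(sprintf("<%s> %s on %s scale (%s)\n",
              paste(setdiff(class(x), c("tbl_df", "tbl", "data.frame")),
                    collapse = "/"),
              x$method[1], x$scale[1], x$exposure_unit[1]))
  NextMethod()
}
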