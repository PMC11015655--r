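test_that("SESOI conversion follows the closed forms", {
  expect_equal(sesoi_to_scale(0.25, "log_or"), 0.25 * pi / sqrt(3),
               tolerance = 1e-12)
  expect_equal(sesoi_to_scale(0.25, "log_or"), 0.4535, tolerance = 2e-4)
  expect_equal(round(sesoi_to_scale(0.23, "beta"), 4), 0.1142)
  expect_equal(sesoi_to_scale(0, "beta"), 0)
  expect_error(sesoi_to_scale(-0.1, "beta"), "non-negative")
})

test_that("inferiority test matches the normal oracle", {
  est <- new_estimate(-0.02, 0.005, 5000, "beta", "per_sd")
  res <- inferiority_test(est, 0.114)
  expect_equal(res$z, (-0.02 + 0.114) / 0.005, tolerance = 1e-10)
  expect_true(res$reject)
  # estimate exactly at the negative bound: p = 0.5, no rejection
  at <- inferiority_test(new_estimate(-0.114, 0.01, 100, "beta", "per_sd"),
                         0.114)
  expect_equal(at$p, 0.5, tolerance = 1e-10)
  expect_false(at$reject)
  # enormous uncertainty: never reject
  wide <- inferiority_test(new_estimate(-0.02, 1e6, 100, "beta", "per_sd"),
                           0.114)
  expect_false(wide$reject)
  expect_error(inferiority_test(
    new_estimate(0, 1, 10, "beta", "per_sd", direction = "two_sided"),
    0.1), "equivalence_test")
})

test_that("TOST equivalence matches the normal oracle", {
  tiny <- equivalence_test(new_estimate(1e-6, 0.001, 100, "beta", "per_sd",
                                        direction = "two_sided"), 0.114)
  expect_true(tiny$reject)
  at <- equivalence_test(new_estimate(0.114, 0.01, 100, "beta", "per_sd",
                                      direction = "two_sided"), 0.114)
  expect_false(at$reject)
  ex <- equivalence_test(new_estimate(0.05, 0.02, 100, "beta", "per_sd",
                                      direction = "two_sided"), 0.114)
  expect_equal(ex$p, 1 - pnorm((0.114 - 0.05) / 0.02), tolerance = 1e-10)
  expect_true(ex$reject)
})

test_that("the decision engine reproduces the registered truth table", {
  spec <- hypothesis_specs()
  h3a <- spec[spec$id == "H3a", ]
  mk <- function(est, se) new_estimate(est, se, 9000, "beta", "per_sd")
  nc_pass <- tibble::tibble(z = 1, p = 0.16, bound = -0.12, pass = TRUE)
  nc_fail <- tibble::tibble(z = 5, p = 1e-7, bound = -0.12, pass = FALSE)
  # mirror of the reported pattern: significant NHST, no SESOI rejection,
  # negative control consistent -> supported
  sig_est <- mk(-0.07, 0.035)       # p_one ~ 0.023, inferiority z small
  d1 <- decide_hypothesis(h3a, sig_est, nc_pass)
  expect_identical(d1$verdict, "supported")
  # equivalence rejection dominates the NHST
  tiny_est <- mk(-0.01, 0.005)      # NHST rejects AND inferiority rejects
  d2 <- decide_hypothesis(h3a, tiny_est, nc_pass)
  expect_identical(d2$verdict, "practically_equivalent_to_0")
  # nothing rejects: undecided
  vague_est <- mk(-0.05, 0.08)
  d3 <- decide_hypothesis(h3a, vague_est, nc_pass)
  expect_identical(d3$verdict, "undecided")
  # significant NHST but failed negative control: not supported
  d4 <- decide_hypothesis(h3a, sig_est, nc_fail)
  expect_identical(d4$verdict, "undecided")
  # negative control required but absent
  expect_error(decide_hypothesis(h3a, sig_est), "negative-control")
  # scale mismatch
  expect_error(decide_hypothesis(
    h3a, new_estimate(-0.07, 0.03, 100, "log_or", "per_sd"), nc_pass),
    "scale")
})

test_that("all 8 combinations map to verdicts with equivalence dominating", {
  spec <- hypothesis_specs()[hypothesis_specs()$id == "H3a", ]
  bound <- sesoi_to_scale(spec$sesoi_d, "beta")   # 0.1240
  # craft estimates hitting each (nhst, equivalence) cell
  cells <- list(
    nhst_eq   = new_estimate(-0.02, 0.004, 9000, "beta", "per_sd"),
    nhst_only = new_estimate(-0.10, 0.030, 9000, "beta", "per_sd"),
    eq_only   = new_estimate(-0.001, 0.010, 9000, "beta", "per_sd"),
    neither   = new_estimate(-0.05, 0.060, 9000, "beta", "per_sd")
  )
  # sanity: the cells are what they claim to be
  expect_true(inferiority_test(cells$nhst_eq, bound)$reject)
  expect_lt(pnorm(cells$nhst_eq$estimate / cells$nhst_eq$se), 0.05)
  expect_false(inferiority_test(cells$nhst_only, bound)$reject)
  expect_true(inferiority_test(cells$eq_only, bound)$reject)
  expect_gt(pnorm(cells$eq_only$estimate / cells$eq_only$se), 0.05)
  expect_false(inferiority_test(cells$neither, bound)$reject)
  for (nc in c(TRUE, FALSE)) {
    ncr <- tibble::tibble(z = 0, p = if (nc) 0.5 else 1e-9, bound = -1,
                          pass = nc)
    verdicts <- vapply(cells, function(e)
      decide_hypothesis(spec, e, ncr)$verdict, character(1))
    expect_identical(unname(verdicts["nhst_eq"]),
                     "practically_equivalent_to_0")
    expect_identical(unname(verdicts["eq_only"]),
                     "practically_equivalent_to_0")
    expect_identical(unname(verdicts["nhst_only"]),
                     if (nc) "supported" else "undecided")
    expect_identical(unname(verdicts["neither"]), "undecided")
  }
  # determinism: identical inputs give identical verdicts
  ncr <- tibble::tibble(z = 0, p = 0.5, bound = -1, pass = TRUE)
  expect_identical(decide_hypothesis(spec, cells$nhst_only, ncr),
                   decide_hypothesis(spec, cells$nhst_only, ncr))
})

test_that("the registered hypothesis table is complete", {
  h <- hypothesis_specs()
  expect_equal(nrow(h), 18)
  expect_true(all(c("H1a", "H1b", "H3a", "H3b", "H4.3b") %in% h$id))
  expect_true(all(h$sesoi_d %in% c(0.23, 0.25, 0.22, 0.20)))
  expect_true(all(h$alpha == 0.05))
  # depression hypotheses are directional, other domains two-sided
  expect_true(all(h$direction[h$domain == "depression"] == "negative"))
  expect_true(all(h$direction[h$domain != "depression"] == "two_sided"))
})
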