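test_that("parameter validation rejects impossible worlds", {
  expect_error(sim_params(maf_range = c(0, 0.6)), "maf_range")
  expect_error(sim_params(target_r2 = 1.2), "target_r2")
  expect_error(sim_params(invalid_fraction = -0.1), "invalid_fraction")
  expect_error(sim_params(prevalence = c(depression = 0)), "prevalence")
  expect_error(sim_params(exposure_sd = NaN), "finite")
  expect_warning(sim_cohort(sim_params(n_individuals = 50, n_snps = 40,
                                       seed = 1)),
                 "weak-instrument")
})

test_that("cohort generation is bit-for-bit reproducible given the seed", {
  p <- sim_params(n_individuals = 400, n_snps = 12, seed = 42)
  a <- sim_cohort(p)
  b <- sim_cohort(p)
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  c2 <- sim_cohort(sim_params(n_individuals = 400, n_snps = 12, seed = 43))
  expect_false(identical(a$exposure_true, c2$exposure_true))
})

test_that("dosages conserve allele frequencies and exposure is calibrated", {
  p <- sim_params(n_individuals = 12000, n_snps = 60, seed = 7)
  co <- sim_cohort(p)
  tru <- attr(co, "truth")
  means <- colMeans(co$dosages)
  se_binom <- sqrt(2 * tru$eaf * (1 - tru$eaf) / nrow(co))
  expect_true(all(abs(means - 2 * tru$eaf) < 3 * se_binom))
  # exposure mean/SD within 2 Monte-Carlo SEs of the configured values
  mc_se_mean <- p$exposure_sd / sqrt(nrow(co))
  expect_lt(abs(mean(co$exposure_true) - 12.69), 2 * mc_se_mean)
  expect_lt(abs(sd(co$exposure_true) - 1.18), 2 * 1.18 / sqrt(2 * nrow(co)))
  # raw depressive symptoms on the right scale, skewed, non-negative
  expect_true(all(co$sym_depression >= 0))
  expect_gt(mean(co$sym_depression), 8.4)
  expect_lt(mean(co$sym_depression), 10)
})

test_that("censoring matches the mass of the exposure above censor_age", {
  co <- sim_cohort(sim_params(n_individuals = 13398, seed = 1))
  expect_identical(is.na(co$exposure_x), co$censored)
  expect_identical(co$censored, co$exposure_true > attr(co, "params")$censor_age)
  # defaults put ~7.25% past the interview age
  expect_lt(abs(mean(co$censored) - 0.0725),
            3 * sqrt(0.0725 * (1 - 0.0725) / nrow(co)))
})

test_that("instrument score R2 hits its target and respects phi", {
  p <- sim_params(n_individuals = 12000, n_snps = 235, seed = 1)
  co <- sim_cohort(p)
  tru <- attr(co, "truth")
  score <- compute_grs(co$dosages, tru$gamma)
  r2 <- cor(score, co$exposure_true)^2
  expect_lt(abs(r2 - 0.069), 0.01)
  # valid world: score uncorrelated with the confounder
  expect_lt(abs(cor(score, co$confounder_u)), 3 / sqrt(nrow(co)))
  # phi != 0: score-confounder correlation near its analytic value
  p2 <- sim_params(n_individuals = 12000, n_snps = 60, phi = 0.3, seed = 2)
  co2 <- sim_cohort(p2)
  sc2 <- compute_grs(co2$dosages, attr(co2, "truth")$gamma)
  expect_gt(cor(sc2, co2$confounder_u), 0.3 - 3 / sqrt(nrow(co2)))
})

test_that("null structure: theta=0 worlds show no exposure-outcome link", {
  p <- sim_params(n_individuals = 8000, n_snps = 30, seed = 3,
                  theta_cont = c(depression = 0, anxiety = 0, cd = 0,
                                 odd = 0, adhd = 0),
                  confounder_effects = c(on_x = 0, on_y = 0, on_y_bin = 0))
  co <- sim_cohort(p)
  y <- standardize(select_transform(co$sym_depression)$y)
  fit <- fit_linear(y, co$exposure_true)
  expect_gt(fit$p_two, 0.01)
})

test_that("summary pairs satisfy E[beta_y] = theta beta_x + alpha", {
  # theta = 0, no pleiotropy: outcome betas centred on zero
  p0 <- sim_params(n_snps = 150, seed = 5,
                   theta_cont = c(depression = 0, anxiety = 0, cd = 0,
                                  odd = 0, adhd = 0))
  sp0 <- sim_summary_pair(p0)
  z <- sp0$outcome_stats$beta / sp0$outcome_stats$se
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  # theta = 0.2 per year, all valid: IVW recovers it within 2 SE
  p1 <- sim_params(n_snps = 150, seed = 6,
                   theta_cont = c(depression = 0.2, anxiety = 0, cd = 0,
                                  odd = 0, adhd = 0))
  ivw <- mr_ivw(wald_ratios(sim_summary_pair(p1)))
  expect_lt(abs(ivw$estimate - 0.2), 2 * ivw$se)
  # directional pleiotropy biases IVW by ~ mean(alpha)/mean(gamma)
  p2 <- sim_params(n_snps = 200, seed = 8, alpha_mean = 0.02,
                   alpha_sd = 0.002, invalid_fraction = 0.3,
                   theta_cont = c(depression = 0, anxiety = 0, cd = 0,
                                  odd = 0, adhd = 0))
  sp2 <- sim_summary_pair(p2)
  tru2 <- attr(sp2, "truth")
  ivw2 <- mr_ivw(wald_ratios(sp2))
  # weighted analytic bias: IVW converges to sum(w g a)/sum(w g^2)
  w <- 1 / (sp2$outcome_stats$se / abs(sp2$exposure_stats$beta))^2
  bias <- sum(w * tru2$alpha / tru2$gamma) / sum(w)
  expect_gt(ivw2$estimate, 0)
  expect_lt(abs(ivw2$estimate - bias), 4 * ivw2$se)
  expect_error(sim_summary_pair(sim_params(n_gwas_outcome = 0)),
               "positive|n_gwas")
})

test_that("GWAS and cohort tables round-trip through delimited files", {
  p <- sim_params(n_individuals = 150, n_snps = 8, seed = 9)
  sp <- sim_summary_pair(p)
  f <- tempfile(fileext = ".tsv")
  write_gwas(sp$exposure_stats, f)
  back <- read_gwas(f)
  expect_equal(back$beta, sp$exposure_stats$beta, tolerance = 1e-12)
  expect_error(read_gwas(write_gwas(sp$exposure_stats[, 1:3], tempfile())),
               "missing columns")
  co <- sim_cohort(p)
  fc <- tempfile()
  write_cohort(co, fc)
  flat <- read_cohort(fc)
  expect_equal(nrow(flat), nrow(co))
  expect_true(all(paste0("g_", colnames(co$dosages)) %in% names(flat)))
  expect_equal(flat$exposure_true, co$exposure_true, tolerance = 1e-9)
})
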