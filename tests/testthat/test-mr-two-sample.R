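test_that("Wald ratios match elementwise arithmetic", {
  pr <- make_pair(beta_x = c(0.1, 0.2), se_x = c(0.01, 0.01),
                  beta_y = c(0.02, 0), se_y = c(0.01, 0.02))
  r <- wald_ratios(pr)
  expect_equal(r$ratio, c(0.2, 0), tolerance = 1e-12)
  expect_equal(r$se, c(0.1, 0.1), tolerance = 1e-12)
  # random case equals a naive loop
  set.seed(1)
  J <- 12
  pr2 <- make_pair(rnorm(J, 0.1, 0.02), runif(J, 0.005, 0.02),
                   rnorm(J, 0.02, 0.01), runif(J, 0.005, 0.02))
  r2 <- wald_ratios(pr2, second_order = TRUE)
  for (j in seq_len(J)) {
    bx <- pr2$exposure_stats$beta[j]; by <- pr2$outcome_stats$beta[j]
    sx <- pr2$exposure_stats$se[j]; sy <- pr2$outcome_stats$se[j]
    expect_equal(r2$ratio[j], by / bx, tolerance = 1e-12)
    expect_equal(r2$se[j], sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4),
                 tolerance = 1e-12)
  }
  # zero exposure beta SNPs are dropped with a log entry
  pr3 <- make_pair(c(0.1, 0), c(0.01, 0.01), c(0.01, 0.01), c(0.01, 0.01))
  expect_message(r3 <- wald_ratios(pr3), "zero exposure")
  expect_equal(nrow(r3), 1)
})

test_that("IVW equals the closed-form weighted mean and Q behaves", {
  r <- tibble::tibble(ratio = c(0.5, 0.3), se = c(0.1, 0.1))
  ivw <- mr_ivw(r, random_effects = FALSE)
  expect_equal(ivw$estimate, 0.4, tolerance = 1e-12)
  expect_equal(ivw$se, 0.1 / sqrt(2), tolerance = 1e-12)
  # identical ratios: zero heterogeneity
  r0 <- tibble::tibble(ratio = rep(0.2, 5), se = runif(5, 0.05, 0.2))
  expect_equal(mr_ivw(r0)$q_stat, 0, tolerance = 1e-12)
  # random case equals the closed form with arbitrary weights
  set.seed(2)
  rr <- tibble::tibble(ratio = rnorm(20, 0.2, 0.1),
                       se = runif(20, 0.05, 0.3))
  w <- 1 / rr$se^2
  ivw2 <- mr_ivw(rr, random_effects = FALSE)
  expect_equal(ivw2$estimate, sum(w * rr$ratio) / sum(w),
               tolerance = 1e-12)
  expect_equal(ivw2$se, sqrt(1 / sum(w)), tolerance = 1e-12)
  expect_equal(ivw2$q_stat, sum(w * (rr$ratio - ivw2$estimate)^2),
               tolerance = 1e-12)
  expect_error(mr_ivw(rr[1, ]), "at least 2")
})

test_that("IVW recovers theta in simulation and matches 2SLS in spirit", {
  p <- sim_params(n_snps = 50, seed = 31,
                  theta_cont = c(depression = 0.2, anxiety = 0, cd = 0,
                                 odd = 0, adhd = 0))
  ivw <- mr_ivw(wald_ratios(sim_summary_pair(p)))
  expect_lt(abs(ivw$estimate - 0.2), 2 * ivw$se)
  # individual-level 2SLS from the same world lands in the same place
  co <- sim_cohort(p)
  sc <- compute_grs(co$dosages, attr(co, "truth")$gamma)
  y <- standardize(select_transform(co$sym_depression)$y)
  iv1 <- mr_tsls(y, co$exposure_true, sc)
  expect_lt(abs(iv1$estimate - ivw$estimate),
            3 * sqrt(iv1$se^2 + ivw$se^2))
})

test_that("MR-Egger reproduces exact fits and reduces to IVW", {
  set.seed(3)
  bx <- runif(8, 0.05, 0.2)
  by <- 0.01 + 0.3 * bx
  pr <- make_pair(bx, rep(0.01, 8), by, rep(0.02, 8))
  eg <- mr_egger(pr)
  expect_equal(eg$estimate, 0.3, tolerance = 1e-8)
  ic <- attr(eg, "egger_intercept")
  expect_equal(ic$estimate, 0.01, tolerance = 1e-8)
  # with the intercept constrained to zero the slope is the IVW estimate
  w <- 1 / pr$outcome_stats$se^2
  slope0 <- sum(w * bx * by) / sum(w * bx^2)
  ivw <- mr_ivw(wald_ratios(pr), random_effects = FALSE)
  expect_equal(slope0, ivw$estimate, tolerance = 1e-10)
  expect_error(mr_egger(make_pair(bx[1:2], rep(0.01, 2), by[1:2],
                                  rep(0.01, 2))), "at least 3")
})

test_that("Egger intercept is centred under balanced pleiotropy and signed
           under directional pleiotropy", {
  covered <- 0
  reps <- 120
  for (r in seq_len(reps)) {
    pb <- sim_params(n_snps = 60, seed = 5000 + r, alpha_mean = 0,
                     alpha_sd = 0.01, invalid_fraction = 1,
                     theta_cont = c(depression = 0.1, anxiety = 0, cd = 0,
                                    odd = 0, adhd = 0))
    eg <- mr_egger(sim_summary_pair(pb))
    ic <- attr(eg, "egger_intercept")
    if (ic$ci_low <= 0 && ic$ci_high >= 0) covered <- covered + 1
  }
  expect_gt(covered / reps, 0.88)
  # directional pleiotropy: intercepts positive on average
  ints <- vapply(1:40, function(r) {
    pd <- sim_params(n_snps = 60, seed = 7000 + r, alpha_mean = 0.02,
                     alpha_sd = 0.005, invalid_fraction = 1,
                     theta_cont = c(depression = 0.1, anxiety = 0, cd = 0,
                                    odd = 0, adhd = 0))
    attr(mr_egger(sim_summary_pair(pd)), "egger_intercept")$estimate
  }, double(1))
  expect_gt(mean(ints), 0)
  expect_gt(mean(ints) / (sd(ints) / sqrt(length(ints))), 3)
})

test_that("weighted median interpolates the cumulative weight function", {
  r <- tibble::tibble(ratio = c(0.1, 0.2, 0.9), se = rep(0.1, 3))
  wm <- mr_weighted_median(r, n_boot = 50, seed = 1)
  expect_equal(wm$estimate, 0.2, tolerance = 1e-12)
  # a SNP holding > 50% of the weight dictates the estimate
  r2 <- tibble::tibble(ratio = c(0.05, 0.7, 0.4), se = c(0.001, 1, 1))
  expect_equal(mr_weighted_median(r2, n_boot = 50, seed = 1)$estimate,
               0.05, tolerance = 1e-4)
  # bootstrap SE is seeded
  a <- mr_weighted_median(r, n_boot = 200, seed = 9)
  b <- mr_weighted_median(r, n_boot = 200, seed = 9)
  expect_identical(a$se, b$se)
  expect_error(mr_weighted_median(r[1:2, ]), "at least 3")
})

test_that("contamination mixture matches a brute-force likelihood scan", {
  # all ratios equal with tiny SEs: estimate pins to that value
  r0 <- tibble::tibble(ratio = rep(0.2, 6), se = rep(0.001, 6))
  cm0 <- mr_conmix(r0)
  expect_equal(cm0$estimate, 0.2, tolerance = 1e-3)
  # CI endpoints agree with a 10x-density independent scan
  set.seed(4)
  r <- tibble::tibble(ratio = c(rnorm(14, 0.2, 0.03), rnorm(6, 0, 0.3)),
                      se = rep(0.05, 20))
  cm <- mr_conmix(r, psi = 0.4, grid_n = 2001)
  fine <- seq(min(r$ratio) - 1, max(r$ratio) + 1, length.out = 20010)
  ll <- vapply(fine, function(th) {
    sum(pmax(dnorm(r$ratio, th, r$se, log = TRUE),
             dnorm(r$ratio, 0, 0.4, log = TRUE)))
  }, double(1))
  keep <- 2 * (max(ll) - ll) <= qchisq(0.95, 1)
  expect_equal(cm$estimate, fine[which.max(ll)], tolerance = 0.01)
  expect_equal(cm$ci_low, min(fine[keep]), tolerance = 0.01)
  expect_equal(cm$ci_high, max(fine[keep]), tolerance = 0.01)
  expect_error(mr_conmix(r[1:2, ]), "at least 3")
})

test_that("contamination mixture recovers theta with 30% scattered
           invalid SNPs", {
  p <- sim_params(n_snps = 100, seed = 62, alpha_mean = 0,
                  alpha_sd = 0.1, invalid_fraction = 0.3,
                  theta_cont = c(depression = 0.2, anxiety = 0, cd = 0,
                                 odd = 0, adhd = 0))
  cm <- mr_conmix(wald_ratios(sim_summary_pair(p)))
  expect_lt(abs(cm$estimate - 0.2), 2.5 * cm$se)
})

test_that("MR-PRESSO flags planted outliers and runs at minimal J", {
  # smoke contract at J = 4
  pr4 <- make_pair(runif(4, 0.05, 0.2), rep(0.01, 4),
                   rnorm(4, 0.02, 0.01), rep(0.01, 4))
  out4 <- mr_presso(pr4, n_sim = 200, seed = 1)
  expect_true(is.finite(out4$global_p))
  expect_gt(out4$global_p, 0)
  expect_lte(out4$global_p, 1)
  # planted outlier: detected by the per-SNP test
  set.seed(5)
  J <- 30
  bx <- runif(J, 0.05, 0.2)
  by <- 0.2 * bx + rnorm(J, 0, 0.01)
  by[7] <- by[7] + 0.25
  pr <- make_pair(bx, rep(0.005, J), by, rep(0.01, J))
  out <- mr_presso(pr, n_sim = 1000, seed = 2)
  expect_true("s7" %in% out$outliers)
  expect_lt(out$global_p, 0.05)
  expect_warning(mr_presso(pr, n_sim = 50, seed = 1), "coarse")
  expect_error(mr_presso(make_pair(bx[1:3], rep(0.01, 3), by[1:3],
                                   rep(0.01, 3)), seed = 1), "at least 4")
})

test_that("MR-PRESSO global p is uniform under homogeneity", {
  reps <- 200
  ps <- vapply(seq_len(reps), function(r) {
    set.seed(9000 + r)
    J <- 20
    bx <- runif(J, 0.05, 0.2)
    by <- 0.2 * bx + rnorm(J, 0, 0.01)
    pr <- make_pair(bx, rep(0.005, J), by, rep(0.01, J))
    mr_presso(pr, n_sim = 199, seed = r)$global_p
  }, double(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("estimators are invariant to SNP relabelling and allele flips", {
  p <- sim_params(n_snps = 40, seed = 63,
                  theta_cont = c(depression = 0.15, anxiety = 0, cd = 0,
                                 odd = 0, adhd = 0))
  pr <- sim_summary_pair(p)
  # simultaneous sign flip of (beta_x, beta_y) for a random subset
  set.seed(6)
  flip <- sample(c(TRUE, FALSE), 40, TRUE)
  pr2 <- pr
  pr2$exposure_stats$beta <- ifelse(flip, -pr$exposure_stats$beta,
                                    pr$exposure_stats$beta)
  pr2$outcome_stats$beta <- ifelse(flip, -pr$outcome_stats$beta,
                                   pr$outcome_stats$beta)
  # and a permutation of SNP order
  perm <- sample(40)
  pr2$exposure_stats <- pr2$exposure_stats[perm, ]
  pr2$outcome_stats <- pr2$outcome_stats[perm, ]
  expect_equal(mr_ivw(wald_ratios(pr2))$estimate,
               mr_ivw(wald_ratios(pr))$estimate, tolerance = 1e-10)
  expect_equal(mr_egger(pr2)$estimate, mr_egger(pr)$estimate,
               tolerance = 1e-10)
  expect_equal(mr_weighted_median(wald_ratios(pr2), 50, seed = 3)$estimate,
               mr_weighted_median(wald_ratios(pr), 50, seed = 3)$estimate,
               tolerance = 1e-10)
})

test_that("MVMR separates direct effects and reduces to IVW", {
  # second exposure with all-zero betas: direct effect of the first equals
  # the univariable IVW estimate (fixed-effect weights)
  set.seed(7)
  J <- 25
  bx <- runif(J, 0.05, 0.2)
  by <- 0.25 * bx + rnorm(J, 0, 0.005)
  pr <- make_pair(bx, rep(0.01, J), by, rep(0.01, J))
  ex2 <- pr$exposure_stats
  ex2$beta <- rnorm(J, 0, 0.001)
  ex2$se <- rep(0.01, J)
  mv <- mr_mvmr(list(aam = pr$exposure_stats, null = ex2),
                pr$outcome_stats)
  ivw <- sum((1 / 0.01^2) * bx * by) / sum((1 / 0.01^2) * bx^2)
  expect_lt(abs(mv$estimate[mv$exposure == "aam"] - ivw), 0.01)
  expect_error(mr_mvmr(list(a = pr$exposure_stats,
                            b = pr$exposure_stats), pr$outcome_stats),
               "Collinear")
})

test_that("MVMR attenuates the total effect toward the direct effect under
           a body-size confounding pathway", {
  p <- sim_params(n_snps = 150, seed = 64)
  mv_dat <- sim_mvmr_stats(p)
  tru <- attr(mv_dat, "truth_effects")
  uni <- mr_ivw(wald_ratios(structure(list(
    exposure_stats = mv_dat$exposures$aam,
    outcome_stats = mv_dat$outcome_stats), class = "summary_pair")))
  mv <- mr_mvmr(mv_dat$exposures, mv_dat$outcome_stats)
  direct_hat <- mv$estimate[mv$exposure == "aam"]
  # univariable IVW tracks the total pathway; MVMR strips the body-size leg
  expect_lt(abs(uni$estimate - tru$total), 3 * uni$se)
  expect_lt(abs(direct_hat - tru$direct),
            3 * mv$se[mv$exposure == "aam"])
  expect_lt(abs(direct_hat - tru$direct), abs(direct_hat - tru$total))
  expect_gt(abs(uni$estimate), abs(direct_hat))
  # residual-heterogeneity (modified Q) diagnostics are attached
  mq <- attr(mv, "modified_q")
  expect_equal(mq$df, 150 - 2)
  expect_true(all(mv$conditional_f > 0))
})

test_that("conditional F tracks the univariable F for independent exposures", {
  set.seed(8)
  J <- 80
  b1 <- rnorm(J, 0.1, 0.05)
  b2 <- rnorm(J, 0.1, 0.05)   # independent of b1
  se1 <- rep(0.01, J)
  e1 <- make_pair(b1, se1, rnorm(J, 0, 0.02), rep(0.02, J))$exposure_stats
  e2 <- e1; e2$beta <- b2
  out <- make_pair(b1, se1, 0.1 * b1 + 0.1 * b2 + rnorm(J, 0, 0.02),
                   rep(0.02, J))$outcome_stats
  mv <- mr_mvmr(list(a = e1, b = e2), out)
  # univariable "F": mean chi-square of b1/se1 about its weighted mean
  w <- 1 / se1^2
  uni_f <- sum(w * (b1 - weighted.mean(b1, w))^2) / (J - 1)
  expect_lt(abs(mv$conditional_f[1] - uni_f) / uni_f, 0.2)
})
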