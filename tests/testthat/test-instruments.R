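test_that("clumping keeps the most significant SNP of a correlated pair", {
  rows <- tibble::tibble(snp = c("a", "b"), chrom = 1,
                         pos = c(1e6, 6e6), pval = c(1e-10, 1e-8))
  ld <- matrix(c(1, 0.5, 0.5, 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(clump_snps(rows, ld)$snp, "a")
  # same LD but 20 Mb apart: outside the 10,000 kb window, both retained
  rows2 <- dplyr::mutate(rows, pos = c(1e6, 21e6))
  expect_identical(sort(clump_snps(rows2, ld)$snp), c("a", "b"))
  expect_error(clump_snps(rows, matrix(c(1, 0.2, 0.5, 1), 2,
                                       dimnames = dimnames(ld))),
               "symmetric")
})

test_that("clumping matches an exhaustive pairwise oracle and is idempotent", {
  for (s in 1:5) {
    set.seed(s)
    J <- 10
    rows <- tibble::tibble(
      snp = paste0("s", 1:J), chrom = sample(1:2, J, TRUE),
      pos = sample.int(3e7, J), pval = runif(J, 1e-12, 1e-4))
    R <- matrix(runif(J * J, 0, 0.8), J)
    R <- (R + t(R)) / 2
    diag(R) <- 1
    dimnames(R) <- list(rows$snp, rows$snp)
    kept <- clump_snps(rows, R, r2_threshold = 0.2, window_kb = 10000)
    expect_true(clump_valid(kept, R, 0.2, 10000))
    # greedy maximality: every dropped SNP conflicts with a retained one
    dropped <- dplyr::anti_join(rows, kept, by = "snp")
    if (nrow(dropped)) {
      conflict <- vapply(seq_len(nrow(dropped)), function(i) {
        any(kept$chrom == dropped$chrom[i] &
              abs(kept$pos - dropped$pos[i]) <= 1e7 &
              R[kept$snp, dropped$snp[i]] >= 0.2)
      }, logical(1))
      expect_true(all(conflict))
    }
    again <- clump_snps(kept, R, r2_threshold = 0.2, window_kb = 10000)
    expect_identical(again$snp, kept$snp)
  }
})

test_that("weighted allele score matches hand arithmetic and a loop oracle", {
  expect_equal(compute_grs(matrix(c(2, 0, 1), 1), c(0.1, 0.2, 0.3)),
               0.5 / 3, tolerance = 1e-12)
  expect_equal(compute_grs(matrix(1, 4, 3), rep(0, 3)), rep(0, 4))
  set.seed(1)
  D <- matrix(sample(0:2, 20, TRUE), 5, 4)
  w <- rnorm(4)
  expect_equal(compute_grs(D, w), grs_loop(D, w), tolerance = 1e-12)
  # linearity in the weights
  expect_equal(compute_grs(D, 3 * w), 3 * compute_grs(D, w),
               tolerance = 1e-12)
  # missing dosages: error unless mean-imputation requested
  D[2, 3] <- NA
  expect_error(compute_grs(D, w), "Missing dosages")
  expect_message(si <- compute_grs(D, w, eaf = rep(0.25, 4),
                                   impute_missing = TRUE),
                 "Mean-imputed")
  D2 <- D; D2[2, 3] <- 0.5
  expect_equal(si, compute_grs(D2, w), tolerance = 1e-12)
})

test_that("residualisation removes nuisance structure exactly", {
  set.seed(2)
  s <- rnorm(60)
  # intercept only: centred score
  expect_equal(residualize_score(s), s - mean(s), tolerance = 1e-12)
  # score an exact linear function of the PCs: residual vanishes
  PC <- matrix(rnorm(60 * 3), 60)
  s2 <- drop(PC %*% c(1, -2, 0.5)) + 4
  expect_lt(max(abs(residualize_score(s2, PC))), 1e-10)
  # random case equals the normal-equations oracle
  res <- residualize_score(s, PC)
  X <- cbind(1, PC)
  expect_equal(res, s - drop(X %*% ols_oracle(s, X)), tolerance = 1e-8)
  for (j in 1:3) expect_lt(abs(cor(res, PC[, j])), 1e-10)
  expect_warning(residualize_score(s, cbind(PC, PC[, 1])), "collinear")
})

test_that("instrument audit reproduces the closed-form F statistic", {
  # F = (R2/1) / ((1-R2)/(n-2)): at R2 = 0.069, n = 13,446 this is ~996.4
  expect_equal(0.069 / ((1 - 0.069) / (13446 - 2)), 996.387, tolerance = 1e-3)
  set.seed(3)
  x <- rnorm(5000)
  s <- 0.2 * x + rnorm(5000)
  a <- audit_instrument(s, x, tibble::tibble(z1 = rnorm(5000),
                                             z2 = rnorm(5000)))
  expect_equal(a$f_stat, (a$r2 / 1) / ((1 - a$r2) / (a$n - 2)),
               tolerance = 1e-12)
  # exposure == score: R2 is 1
  expect_equal(audit_instrument(x, x)$r2, 1, tolerance = 1e-12)
  # null covariates show no associations beyond chance
  expect_true(all(a$associations$p > 0.001))
  expect_message(audit_instrument(s, x, tibble::tibble(cst = rep(1, 5000))),
                 "zero-variance")
})

test_that("Steiger filtering removes outcome-predictive SNPs", {
  # direction-only trivial cases
  pr <- make_pair(beta_x = c(0.10, 0.01), se_x = c(0.01, 0.01),
                  beta_y = c(0.01, 0.10), se_y = c(0.01, 0.01),
                  n_x = 10000, n_y = 10000)
  out <- steiger_filter(pr)
  expect_identical(out$exposure_stats$snp, "s1")
  log <- attr(out, "removal_log")
  expect_identical(log$removed, c(FALSE, TRUE))
  # simulated reverse-causal SNPs are removed preferentially
  set.seed(4)
  J <- 200
  rev <- seq_len(J) <= 60
  bx <- ifelse(rev, rnorm(J, 0.01, 0.002), rnorm(J, 0.08, 0.01))
  by <- ifelse(rev, rnorm(J, 0.08, 0.01), rnorm(J, 0.01, 0.005))
  pr2 <- make_pair(bx, rep(0.004, J), by, rep(0.004, J),
                   n_x = 50000, n_y = 50000)
  out2 <- steiger_filter(pr2)
  lg <- attr(out2, "removal_log")
  expect_gt(mean(lg$removed[rev]), 0.5)
  expect_lt(mean(lg$removed[!rev]), 0.1)
  # ties retain the SNP
  tie <- make_pair(0.05, 0.01, 0.05, 0.01, n_x = 1000, n_y = 1000)
  expect_equal(nrow(steiger_filter(tie)$exposure_stats), 1)
  # missing n is an error
  pr3 <- pr
  pr3$outcome_stats$n <- NA_integer_
  expect_error(steiger_filter(pr3), "requires `n`")
})
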