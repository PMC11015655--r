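# Independent oracles used across tests. These deliberately use naive
# loops / closed forms rather than the package's own code paths.

# naive per-individual loop for the weighted allele score
grs_loop <- function(dosages, weights) {
  n <- nrow(dosages)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(ncol(dosages))) s <- s + dosages[i, j] * weights[j]
    out[i] <- s / length(weights)
  }
  out
}

# normal-equations least squares (coefficients only)
ols_oracle <- function(y, X) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# brute-force validity check of a clumped set: every retained pair within
# the window must have LD below the threshold
clump_valid <- function(retained, ld, r2_threshold, window_kb) {
  if (nrow(retained) < 2) return(TRUE)
  for (i in 1:(nrow(retained) - 1)) {
    for (k in (i + 1):nrow(retained)) {
      if (retained$chrom[i] != retained$chrom[k]) next
      if (abs(retained$pos[i] - retained$pos[k]) > window_kb * 1000) next
      r2 <- ld[retained$snp[i], retained$snp[k]]
      if (r2 >= r2_threshold) return(FALSE)
    }
  }
  TRUE
}

# build a small aligned summary pair directly from given vectors
make_pair <- function(beta_x, se_x, beta_y, se_y, n_x = 100000,
                      n_y = 10000) {
  J <- length(beta_x)
  mk <- function(b, s, n) {
    tibble::tibble(
      snp = paste0("s", seq_len(J)), chrom = 1L,
      pos = seq_len(J) * 1e6 + 1e8,
      effect_allele = "A", other_allele = "G", eaf = 0.3,
      beta = b, se = s, pval = 2 * pnorm(-abs(b / s)), n = n
    )
  }
  structure(list(exposure_stats = mk(beta_x, se_x, n_x),
                 outcome_stats = mk(beta_y, se_y, n_y),
                 n_exposure = n_x, n_outcome = n_y),
            class = "summary_pair")
}
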