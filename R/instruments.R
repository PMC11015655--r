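#' Greedy LD clumping of GWAS summary rows
#'
#' Retains a set of approximately independent SNPs by greedily keeping the
#' most significant SNP and discarding any SNP within `window_kb` of a
#' retained SNP whose LD r-squared with it is at least `r2_threshold`
#' (defaults mirror common practice: r2 = 0.001, 10,000 kb window). Ties on
#' p-value break deterministically on lower chromosome then position. SNPs
#' absent from the LD matrix are treated as independent and logged.
#'
#' @param rows GWAS summary tibble with `snp`, `chrom`, `pos`, `pval`.
#' @param ld SNP-by-SNP r-squared matrix with dimnames; symmetric, unit
#'   diagonal. Use `NULL` (or a 0-row matrix) for fully independent panels.
#' @param r2_threshold LD r-squared above which a nearby SNP is discarded.
#' @param window_kb Clumping window in kilobases.
#' @return The retained rows, in retention (greedy) order, with attribute
#'   `log` listing SNPs missing from `ld`.
#' @examples
#' rows <- tibble::tibble(snp = c("a", "b"), chrom = 1,
#'                        pos = c(1e6, 6e6), pval = c(1e-10, 1e-8))
#' ld <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("a","b"), c("a","b")))
#' clump_snps(rows, ld)$snp
#' @export
clump_snps <- function(rows, ld = NULL, r2_threshold = 0.001,
                       window_kb = 10000) {
  stopifnot(all(c("snp", "chrom", "pos", "pval") %in% names(rows)))
  if (!is.null(ld) && nrow(ld) > 0) {
    if (!isTRUE(all.equal(ld, t(ld), tolerance = 1e-8)) ||
        any(abs(diag(ld) - 1) > 1e-8)) {
      abort("`ld` must be symmetric with unit diagonal.")
    }
  }
  ord <- order(rows$pval, rows$chrom, rows$pos)
  rows <- rows[ord, , drop = FALSE]
  missing_ld <- character()
  kept <- integer()
  for (i in seq_len(nrow(rows))) {
    ok <- TRUE
    for (k in kept) {
      if (rows$chrom[i] != rows$chrom[k]) next
      if (abs(rows$pos[i] - rows$pos[k]) > window_kb * 1000) next
      r2 <- NA_real_
      if (!is.null(ld) && rows$snp[i] %in% rownames(ld) &&
          rows$snp[k] %in% rownames(ld)) {
        r2 <- ld[rows$snp[i], rows$snp[k]]
      } else {
        missing_ld <- union(missing_ld, setdiff(c(rows$snp[i], rows$snp[k]),
                                                rownames(ld)))
      }
      if (!is.na(r2) && r2 >= r2_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- rows[kept, , drop = FALSE]
  if (length(missing_ld)) {
    inform(paste0("SNPs missing from LD matrix (treated as independent): ",
                  paste(missing_ld, collapse = ", ")))
  }
  attr(out, "log") <- missing_ld
  out
}

#' Weighted allele score
#'
#' Multiplies each individual's effect-allele dosage (0, 1 or 2, or imputed
#' probabilities) by the SNP's external GWAS weight, sums across SNPs and
#' divides by the number of SNPs: `score_i = sum_j d_ij w_j / J`.
#'
#' @param dosages n x J numeric matrix with values in \[0, 2\].
#' @param weights Length-J per-SNP effect sizes.
#' @param eaf Optional effect-allele frequencies used to mean-impute missing
#'   dosages as `2 * eaf` when `impute_missing = TRUE`.
#' @param impute_missing Substitute `2 * eaf` for missing dosages (logged);
#'   otherwise missing dosages are an error.
#' @return Numeric score vector of length n.
#' @examples
#' compute_grs(matrix(c(2, 0, 1), 1), c(0.1, 0.2, 0.3))
#' @export
compute_grs <- function(dosages, weights, eaf = NULL,
                        impute_missing = FALSE) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != length(weights)) {
    abort("Number of dosage columns must equal number of weights.")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) abort("Dosages must lie in [0, 2].")
  if (anyNA(dosages)) {
    if (!impute_missing) {
      abort("Missing dosages; set `impute_missing = TRUE` with `eaf`.")
    }
    if (is.null(eaf) || length(eaf) != ncol(dosages)) {
      abort("`eaf` of length ncol(dosages) required to impute.")
    }
    n_imp <- sum(is.na(dosages))
    idx <- which(is.na(dosages), arr.ind = TRUE)
    dosages[idx] <- 2 * eaf[idx[, 2]]
    inform(sprintf("Mean-imputed %d missing dosages as 2*eaf.", n_imp))
  }
  drop(dosages %*% weights) / length(weights)
}

#' Residualise a score on nuisance covariates
#'
#' Regresses the genetic score on nuisance terms (genotyping batch
#' indicators and principal components) and returns the residual, removing
#' batch effects and population-stratification axes from the instrument.
#' Collinear nuisance columns are dropped with a warning.
#'
#' @param score Numeric vector.
#' @param nuisance Numeric matrix or data frame of nuisance covariates; an
#'   intercept is always included.
#' @return Residual vector, orthogonal to every retained nuisance column and
#'   centred at zero.
#' @examples
#' residualize_score(rnorm(10), matrix(rnorm(10), 10, 1))
#' @export
residualize_score <- function(score, nuisance = NULL) {
  n <- length(score)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (is.null(colnames(nuisance))) {
      colnames(nuisance) <- paste0("z", seq_len(ncol(nuisance)))
    }
    X <- cbind(X, nuisance)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warn(paste0("Dropping collinear nuisance columns: ",
                paste(dropped, collapse = ", ")))
  }
  qr.resid(qx, score)
}

#' Instrument relevance and covariate audit
#'
#' Reports the variance in the exposure explained by the score
#' (`r2 = cor(score, x)^2`), the single-instrument first-stage F statistic
#' `F = R2 (n - 2) / (1 - R2)`, and a table of standardised associations of
#' the score with each measured covariate (a valid instrument should show
#' none beyond chance).
#'
#' @param score Genetic score vector.
#' @param exposure_x Exposure vector (may contain `NA` from censoring;
#'   complete pairs are used).
#' @param covariates Optional data frame of covariates to audit.
#' @param level Confidence level for covariate association intervals.
#' @return A list with `r2`, `f_stat`, `n`, and tibble `associations`
#'   (covariate, standardised beta, SE, CI, p). Zero-variance covariates are
#'   skipped with a message.
#' @examples
#' x <- rnorm(200); s <- 0.3 * x + rnorm(200)
#' audit_instrument(s, x)$f_stat
#' @export
audit_instrument <- function(score, exposure_x, covariates = NULL,
                             level = 0.95) {
  ok <- is.finite(score) & is.finite(exposure_x)
  if (sum(ok) < 30) abort("Need at least 30 complete score/exposure pairs.")
  s <- score[ok]; x <- exposure_x[ok]
  r2 <- cor(s, x)^2
  n <- sum(ok)
  f_stat <- (r2 / 1) / ((1 - r2) / (n - 2))
  assoc <- tibble::tibble(covariate = character(), beta = double(),
                          se = double(), ci_low = double(),
                          ci_high = double(), p = double())
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    zc <- qnorm(1 - (1 - level) / 2)
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      okv <- is.finite(score) & is.finite(v)
      if (sd(v[okv]) == 0) {
        inform(sprintf("Skipping zero-variance covariate '%s'.", nm))
        next
      }
      zs <- as.numeric(scale(score[okv]))
      zv <- as.numeric(scale(v[okv]))
      fit <- lm.fit(cbind(1, zs), zv)
      b <- fit$coefficients[2]
      sig2 <- sum(fit$residuals^2) / (length(zv) - 2)
      seb <- sqrt(sig2 / sum((zs - mean(zs))^2))
      assoc <- dplyr::bind_rows(assoc, tibble::tibble(
        covariate = nm, beta = b, se = seb,
        ci_low = b - zc * seb, ci_high = b + zc * seb,
        p = 2 * pnorm(-abs(b / seb))
      ))
    }
  }
  list(r2 = r2, f_stat = f_stat, n = n, associations = assoc)
}

#' Steiger filtering of a summary pair
#'
#' Removes SNPs that explain more variance in the outcome than in the
#' exposure, guarding against reverse causation. Per-SNP variance explained
#' is computed from the z-statistic as `r2 = z^2 / (z^2 + n)`, which is
#' robust to missing allele frequencies. Ties (`r2` equal) retain the SNP.
#' Optionally, removal additionally requires the difference in the implied
#' correlations to be significant by Steiger's z-test (Fisher
#' transformation) at `sig_level`.
#'
#' @param pair A `summary_pair` (see [sim_summary_pair()]) or a list with
#'   aligned `exposure_stats` and `outcome_stats` tibbles carrying `beta`,
#'   `se`, `n`.
#' @param require_significance If `TRUE`, only remove SNPs whose
#'   outcome-vs-exposure r2 difference is significant (direction-only is the
#'   default).
#' @param sig_level Significance level for the optional Steiger z-test.
#' @return The filtered pair, with attribute `removal_log`: a tibble of SNPs
#'   with both r2 values, the Steiger z, and whether each was removed.
#' @export
steiger_filter <- function(pair, require_significance = FALSE,
                           sig_level = 0.05) {
  ex <- pair$exposure_stats; ou <- pair$outcome_stats
  check_aligned(ex, ou)
  if (anyNA(ex$n) || anyNA(ou$n)) {
    abort("Steiger filtering requires `n` on both sides.")
  }
  r2_of <- function(tab) {
    z <- tab$beta / tab$se
    z^2 / (z^2 + tab$n)
  }
  r2x <- r2_of(ex); r2y <- r2_of(ou)
  rx <- sqrt(r2x); ry <- sqrt(r2y)
  steiger_z <- (atanh(rx) - atanh(ry)) /
    sqrt(1 / (ex$n - 3) + 1 / (ou$n - 3))
  remove <- r2y > r2x
  if (require_significance) {
    remove <- remove & (pnorm(steiger_z) < sig_level)
  }
  log <- tibble::tibble(snp = ex$snp, r2_exposure = r2x, r2_outcome = r2y,
                        steiger_z = steiger_z, removed = remove)
  out <- pair
  out$exposure_stats <- ex[!remove, , drop = FALSE]
  out$outcome_stats <- ou[!remove, , drop = FALSE]
  attr(out, "removal_log") <- log
  if (!is.null(attr(pair, "truth"))) {
    attr(out, "truth") <- attr(pair, "truth")[!remove, , drop = FALSE]
  }
  out
}

check_aligned <- function(ex, ou) {
  if (nrow(ex) != nrow(ou) || any(ex$snp != ou$snp)) {
    abort("Exposure and outcome tables must be aligned on the same SNPs.")
  }
  if ("effect_allele" %in% names(ex) && "effect_allele" %in% names(ou) &&
      any(ex$effect_allele != ou$effect_allele)) {
    abort("Exposure and outcome tables must share effect-allele orientation.")
  }
  if (any(ex$se <= 0) || any(ou$se <= 0)) abort("All SEs must be positive.")
  invisible(TRUE)
}
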