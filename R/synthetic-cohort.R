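#' Simulation parameters for the synthetic cohort
#'
#' Bundles every knob of the synthetic-data world into a validated list. The
#' defaults reproduce the structure of the motivating adolescent cohort:
#' 13,398 girls; age at menarche with mean 12.69 and SD 1.18 years,
#' right-censored above `censor_age` (default 14.41 y, the value at which
#' 7.25% of a Normal(12.69, 1.18^2) exposure is still unobserved — matching
#' questionnaires returned at about age 14.4); an instrument of 235
#' independent SNPs explaining 6.9% of exposure variance; a raw depressive
#' symptom scale with mean 9.20 and SD 6.56 (right-skewed); depression
#' diagnoses at 5.2% prevalence; a continuous confounder (childhood body
#' size proxy) acting on both exposure and outcomes; pre-pubertal symptom
#' scores (mean 5.71, SD 4.93) as negative-control outcomes; and selective
#' attrition driven by baseline covariates.
#'
#' Causal effects default to the study's calibration targets: a per-year
#' effect on standardised depressive symptoms of -0.07/1.18 (the one-sample
#' MR beta of -0.07 per SD of exposure) and a per-year log odds ratio of
#' log(0.74)/1.18 for depression diagnoses; other domains default to no
#' effect.
#'
#' @param n_individuals Cohort size.
#' @param n_snps Number of independent instrument SNPs.
#' @param maf_range Range of minor allele frequencies, in (0, 0.5].
#' @param exposure_mean,exposure_sd Age at menarche distribution (years).
#' @param target_r2 Fraction of exposure variance explained by the weighted
#'   allele score.
#' @param theta_cont Named per-domain causal effects on continuous symptom
#'   outcomes, in SD of outcome per *year* of age at menarche.
#' @param theta_bin Named per-domain causal log odds ratios per year.
#' @param alpha_mean,alpha_sd Mean and SD of per-SNP direct (pleiotropic)
#'   effects on the outcome for invalid SNPs; `alpha_mean != 0` gives
#'   directional pleiotropy, `alpha_mean == 0, alpha_sd > 0` balanced.
#' @param invalid_fraction Proportion of SNPs with a nonzero direct effect.
#' @param phi Instrument-confounder dependence: correlation between the
#'   (standardised) true genetic score and the confounder; 0 in valid
#'   instrument scenarios.
#' @param confounder_effects Named vector: `on_x` (years per SD of
#'   confounder), `on_y` (SD of continuous outcome per SD), `on_y_bin`
#'   (log-odds per SD).
#' @param prevalence Named baseline prevalences of the binary diagnostic
#'   outcomes.
#' @param cont_scales Named list of `c(mean, sd)` raw-scale targets for the
#'   continuous symptom outcomes.
#' @param negcontrol_scale `c(mean, sd)` of the pre-pubertal (age 8) symptom
#'   scores.
#' @param censor_age Exposure value above which menarche is unobserved at
#'   interview (years).
#' @param attrition_coefs Named log-odds coefficients of the participation
#'   model (`intercept`, `u`, `edu`, `income`).
#' @param n_gwas_exposure,n_gwas_outcome Sample sizes behind the simulated
#'   exposure-side and outcome-side GWAS summary statistics.
#' @param seed Integer seed; every generator call is deterministic given it.
#'
#' @return A validated list of class `sim_params`.
#' @examples
#' p <- sim_params(n_individuals = 500, n_snps = 20, seed = 1)
#' p$target_r2
#' @export
sim_params <- function(n_individuals = 13398,
                       n_snps = 235,
                       maf_range = c(0.1, 0.5),
                       exposure_mean = 12.69,
                       exposure_sd = 1.18,
                       target_r2 = 0.069,
                       theta_cont = c(depression = -0.07 / 1.18, anxiety = 0,
                                      cd = 0, odd = 0, adhd = 0),
                       theta_bin = c(depression = log(0.74) / 1.18,
                                     anxiety = 0, dbd = 0, adhd = 0),
                       alpha_mean = 0,
                       alpha_sd = 0,
                       invalid_fraction = 0,
                       phi = 0,
                       confounder_effects = c(on_x = -0.2, on_y = 0.15,
                                              on_y_bin = 0.25),
                       prevalence = c(depression = 0.052, anxiety = 0.04,
                                      dbd = 0.015, adhd = 0.03),
                       cont_scales = list(
                         depression = c(mean = 9.20, sd = 6.56),
                         anxiety = c(mean = 3.5, sd = 2.8),
                         cd = c(mean = 4.0, sd = 3.6),
                         odd = c(mean = 5.0, sd = 4.0),
                         adhd = c(mean = 8.0, sd = 6.0)),
                       negcontrol_scale = c(mean = 5.71, sd = 4.93),
                       censor_age = 12.69 + qnorm(1 - 0.0725) * 1.18,
                       attrition_coefs = c(intercept = 1.5, u = -0.4,
                                           edu = 0.3, income = 0.2),
                       n_gwas_exposure = 329345,
                       n_gwas_outcome = 9832,
                       seed = 1L) {
  p <- list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    maf_range = maf_range, exposure_mean = exposure_mean,
    exposure_sd = exposure_sd, target_r2 = target_r2,
    theta_cont = theta_cont, theta_bin = theta_bin,
    alpha_mean = alpha_mean, alpha_sd = alpha_sd,
    invalid_fraction = invalid_fraction, phi = phi,
    confounder_effects = confounder_effects, prevalence = prevalence,
    cont_scales = cont_scales, negcontrol_scale = negcontrol_scale,
    censor_age = censor_age, attrition_coefs = attrition_coefs,
    n_gwas_exposure = as.integer(n_gwas_exposure),
    n_gwas_outcome = as.integer(n_gwas_outcome), seed = seed
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  num <- unlist(p[c("maf_range", "exposure_mean", "exposure_sd", "target_r2",
                    "theta_cont", "theta_bin", "alpha_mean", "alpha_sd",
                    "invalid_fraction", "phi", "confounder_effects",
                    "prevalence", "censor_age", "attrition_coefs")])
  if (any(!is.finite(num))) abort("All simulation parameters must be finite.")
  if (length(p$maf_range) != 2 || any(p$maf_range <= 0) ||
      any(p$maf_range > 0.5) || p$maf_range[1] > p$maf_range[2]) {
    abort("`maf_range` must be an increasing pair in (0, 0.5].")
  }
  if (p$target_r2 <= 0 || p$target_r2 >= 1) {
    abort("`target_r2` must be in (0, 1).")
  }
  if (p$invalid_fraction < 0 || p$invalid_fraction > 1) {
    abort("`invalid_fraction` must be in [0, 1].")
  }
  if (any(p$prevalence <= 0 | p$prevalence >= 1)) {
    abort("`prevalence` values must be in (0, 1).")
  }
  if (abs(p$phi) >= 1) abort("`phi` must be in (-1, 1).")
  if (p$n_individuals < 2) abort("`n_individuals` must be at least 2.")
  if (p$n_snps < 1) abort("`n_snps` must be at least 1.")
  invisible(p)
}

# Draw the SNP panel shared by cohort and summary statistics: positions,
# alleles, frequencies, and true per-SNP effects scaled so the weighted score
# explains exactly `target_r2` of the exposure variance in the population.
sim_snp_panel <- function(p) {
  J <- p$n_snps
  maf <- runif(J, p$maf_range[1], p$maf_range[2])
  chrom <- sort(sample(1:22, J, replace = TRUE))
  pos <- integer(J)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- sort(sample.int(2.4e8, length(idx)))
  }
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, J, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1), character(1))
  gamma_raw <- abs(rnorm(J)) + 0.1
  gvar <- sum(gamma_raw^2 * 2 * maf * (1 - maf))
  gamma <- gamma_raw * sqrt(p$target_r2 * p$exposure_sd^2 / gvar)
  invalid <- rep(FALSE, J)
  n_inv <- round(p$invalid_fraction * J)
  if (n_inv > 0) invalid[sample.int(J, n_inv)] <- TRUE
  alpha <- ifelse(invalid, rnorm(J, p$alpha_mean, p$alpha_sd), 0)
  tibble::tibble(
    snp = sprintf("rs%07d", sample.int(9.9e6, J)),
    chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = unname(oa),
    eaf = maf, gamma = gamma, alpha = alpha, invalid = invalid
  )
}

#' Generate a synthetic individual-level cohort
#'
#' Simulates genotype dosages (independent loci, Binomial(2, maf) — the
#' post-clumping world), the confounded exposure, skewed continuous symptom
#' scores, rare binary diagnoses, pre-pubertal negative-control scores,
#' nuisance covariates (parental education/income analogues, genotyping
#' batch, 20 principal components), right-censoring of the exposure at
#' interview, and covariate-driven participation.
#'
#' The true (uncensored) exposure is retained in `exposure_true` so that
#' imputation accuracy can be scored in simulation; analyses must use
#' `exposure_x`, which is `NA` wherever `censored` is `TRUE`.
#'
#' @param params A [sim_params()] object.
#' @return A tibble of class `aam_cohort` with one row per individual, a
#'   matrix column `dosages` (n x J, values 0/1/2), and an attribute `truth`
#'   (the SNP panel with true effects). Columns include `exposure_x`,
#'   `exposure_true`, `censored`, `confounder_u`, `sym_<domain>`,
#'   `diag_<domain>`, `neg_<domain>`, covariates, and `participation`.
#' @examples
#' co <- sim_cohort(sim_params(n_individuals = 300, n_snps = 10, seed = 7))
#' mean(co$censored)
#' @export
sim_cohort <- function(params) {
  p <- validate_sim_params(params)
  if (p$n_individuals < 2 * p$n_snps) {
    warn("n_individuals < 2 * n_snps: weak-instrument regime.")
  }
  with_seed(p$seed, {
    n <- p$n_individuals
    panel <- sim_snp_panel(p)
    J <- nrow(panel)
    G <- matrix(rbinom(n * J, 2L, rep(panel$eaf, each = n)), nrow = n)
    colnames(G) <- panel$snp
    Gc <- sweep(G, 2, 2 * panel$eaf)

    # true genetic component of the exposure (years)
    gx <- drop(Gc %*% panel$gamma)
    gx_sd <- sqrt(sum(panel$gamma^2 * 2 * panel$eaf * (1 - panel$eaf)))

    # confounder: childhood body size proxy, optionally correlated with the
    # instrument through phi
    u <- if (p$phi != 0) {
      p$phi * gx / gx_sd + sqrt(1 - p$phi^2) * rnorm(n)
    } else rnorm(n)

    ce <- p$confounder_effects
    resid_var <- p$exposure_sd^2 - gx_sd^2 - ce[["on_x"]]^2
    if (resid_var <= 0) {
      abort("Genetic and confounder variance exceed the exposure variance.")
    }
    x <- p$exposure_mean + gx + ce[["on_x"]] * u +
      rnorm(n, sd = sqrt(resid_var))
    xc_year <- x - p$exposure_mean

    # covariates
    edu <- pmin(pmax(round(rnorm(n, 3, 1)), 1), 5)
    income <- rnorm(n)
    parity <- rbinom(n, 4, 0.35)
    mat_age <- rnorm(n, 30, 4.5)
    batch <- sample.int(3, n, replace = TRUE)
    PC <- matrix(rnorm(n * 20), n, 20,
                 dimnames = list(NULL, paste0("pc", 1:20)))

    # continuous symptom outcomes: standardised latent then raw skewed scale
    pleio <- drop(Gc %*% panel$alpha)
    cont <- purrr::imap(p$theta_cont, function(th, dom) {
      lat <- th * xc_year + ce[["on_y"]] * u +
        (if (dom == "depression") pleio else 0)
      lat <- lat + rnorm(n)
      lat <- (lat - mean(lat)) / sd(lat)
      sc <- p$cont_scales[[dom]]
      latent_to_skewed(lat, sc[["mean"]], sc[["sd"]])
    })

    # binary diagnoses: logistic link, intercept solved for prevalence
    bin <- purrr::imap(p$theta_bin, function(th, dom) {
      lp <- th * xc_year + ce[["on_y_bin"]] * u
      b0 <- solve_intercept(lp, p$prevalence[[dom]])
      rbinom(n, 1L, plogis(b0 + lp))
    })

    # pre-pubertal negative controls: confounder only, never the exposure
    neg <- purrr::map(p$theta_cont, function(th) {
      lat <- ce[["on_y"]] * u + rnorm(n)
      lat <- (lat - mean(lat)) / sd(lat)
      latent_to_skewed(lat, p$negcontrol_scale[["mean"]],
                       p$negcontrol_scale[["sd"]])
    })

    # censoring at interview and covariate-driven participation (MAR)
    censored <- x > p$censor_age
    ac <- p$attrition_coefs
    part_lp <- ac[["intercept"]] + ac[["u"]] * u +
      ac[["edu"]] * (edu - 3) + ac[["income"]] * income
    participation <- runif(n) < plogis(part_lp)

    out <- tibble::tibble(
      id = seq_len(n),
      exposure_x = ifelse(censored, NA_real_, x),
      exposure_true = x,
      censored = censored,
      confounder_u = u,
      edu = as.numeric(edu), income = income,
      parity = as.numeric(parity), mat_age = mat_age,
      batch = batch,
      participation = participation
    )
    for (dom in names(cont)) out[[paste0("sym_", dom)]] <- cont[[dom]]
    for (dom in names(bin)) out[[paste0("diag_", dom)]] <- bin[[dom]]
    for (dom in names(neg)) out[[paste0("neg_", dom)]] <- neg[[dom]]
    out$pcs <- PC
    out$dosages <- G
    attr(out, "truth") <- panel
    attr(out, "params") <- p
    class(out) <- c("aam_cohort", class(out))
    out
  })
}

#' Generate a paired set of exposure and outcome GWAS summary statistics
#'
#' Produces the two-sample MR input: per-SNP associations with the exposure
#' (years per effect allele, from a large external GWAS) and with one outcome
#' (SD units per allele, from a within-cohort GWAS), aligned on SNP id and
#' effect allele. Outcome-side expectations satisfy
#' `E[beta_y] = theta * beta_x + alpha_j`; standard errors scale as
#' `1/sqrt(2 * eaf * (1 - eaf) * N)`.
#'
#' @param params A [sim_params()] object.
#' @param outcome Continuous outcome domain for the outcome-side GWAS.
#' @return A list of class `summary_pair` with tibbles `exposure_stats` and
#'   `outcome_stats` (columns `snp`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) plus the true panel in
#'   attribute `truth`.
#' @examples
#' sp <- sim_summary_pair(sim_params(n_snps = 25, seed = 3))
#' head(sp$exposure_stats)
#' @export
sim_summary_pair <- function(params, outcome = "depression") {
  p <- validate_sim_params(params)
  if (p$n_gwas_outcome <= 0) abort("`n_gwas_outcome` must be positive.")
  if (!outcome %in% names(p$theta_cont)) {
    abort(sprintf("Unknown outcome domain '%s'.", outcome))
  }
  # the SNP panel is drawn from the same stream as sim_cohort() so the
  # exposure-side weights refer to the cohort's own loci
  panel <- with_seed(p$seed, sim_snp_panel(p))
  with_seed(child_seed(p$seed, 17L), {
    v <- 2 * panel$eaf * (1 - panel$eaf)
    se_x <- p$exposure_sd / sqrt(v * p$n_gwas_exposure)
    beta_x <- rnorm(nrow(panel), panel$gamma, se_x)
    theta <- p$theta_cont[[outcome]]
    se_y <- 1 / sqrt(v * p$n_gwas_outcome)
    beta_y <- rnorm(nrow(panel), theta * panel$gamma + panel$alpha, se_y)
    mk <- function(beta, se, n) {
      tibble::tibble(
        snp = panel$snp, chrom = panel$chrom, pos = panel$pos,
        effect_allele = panel$effect_allele,
        other_allele = panel$other_allele,
        eaf = panel$eaf, beta = beta, se = se,
        pval = 2 * pnorm(-abs(beta / se)), n = n
      )
    }
    out <- list(
      exposure_stats = mk(beta_x, se_x, p$n_gwas_exposure),
      outcome_stats = mk(beta_y, se_y, p$n_gwas_outcome),
      n_exposure = p$n_gwas_exposure,
      n_outcome = p$n_gwas_outcome
    )
    attr(out, "truth") <- panel
    class(out) <- "summary_pair"
    out
  })
}

#' Generate summary statistics for a multivariable MR scenario
#'
#' Emulates the confounding-by-body-size pathway: the age-at-menarche SNPs
#' also influence childhood body size (`b_j = kappa * gamma_j + eta_j`),
#' and body size has its own effect `lambda` on the outcome, so the
#' *univariable* menarche-outcome analysis estimates the total pathway
#' `theta + lambda * kappa` while the multivariable model can separate the
#' direct effect `theta` from the body-size route.
#'
#' @param params A [sim_params()] object (`theta_cont[["depression"]]` is
#'   the direct effect).
#' @param kappa Per-unit sharing of genetic effects with body size; the
#'   negative default encodes larger childhood body size going with
#'   *earlier* menarche, so the indirect path inflates the negative total
#'   effect that multivariable adjustment then attenuates.
#' @param lambda Effect of body size on the outcome (SD per unit).
#' @param eta_sd SD of the body-size-specific genetic component.
#' @return List with `exposures` (named list of aligned summary tibbles for
#'   `aam` and `bodysize`), `outcome_stats`, and the true effects in
#'   attribute `truth_effects`.
#' @export
sim_mvmr_stats <- function(params, kappa = -0.6, lambda = 0.15,
                           eta_sd = NULL) {
  p <- validate_sim_params(params)
  panel <- with_seed(p$seed, sim_snp_panel(p))
  with_seed(child_seed(p$seed, 31L), {
    v <- 2 * panel$eaf * (1 - panel$eaf)
    # most of the body-size genetic architecture is independent of the
    # menarche loci; the shared part (kappa) is what MVMR must strip out
    eta_sd <- eta_sd %||% (2 * sd(panel$gamma))
    b_body <- kappa * panel$gamma + rnorm(nrow(panel), 0, eta_sd)
    theta <- p$theta_cont[["depression"]]
    se_x <- p$exposure_sd / sqrt(v * p$n_gwas_exposure)
    se_b <- 1 / sqrt(v * p$n_gwas_exposure)
    se_y <- 1 / sqrt(v * p$n_gwas_outcome)
    mk <- function(true_beta, se, n) {
      tibble::tibble(
        snp = panel$snp, chrom = panel$chrom, pos = panel$pos,
        effect_allele = panel$effect_allele,
        other_allele = panel$other_allele, eaf = panel$eaf,
        beta = rnorm(nrow(panel), true_beta, se), se = se,
        pval = NA_real_, n = n
      ) |>
        dplyr::mutate(pval = 2 * pnorm(-abs(beta / se)))
    }
    out <- list(
      exposures = list(
        aam = mk(panel$gamma, se_x, p$n_gwas_exposure),
        bodysize = mk(b_body, se_b, p$n_gwas_exposure)
      ),
      outcome_stats = mk(theta * panel$gamma + lambda * b_body +
                           panel$alpha, se_y, p$n_gwas_outcome)
    )
    attr(out, "truth_effects") <- list(direct = theta, lambda = lambda,
                                       kappa = kappa,
                                       total = theta + lambda * kappa)
    out
  })
}

#' Read or write cohort and GWAS summary tables
#'
#' Cohorts are serialised as tab-delimited tables, one row per individual,
#' with dosage and principal-component matrix columns flattened to `g_<snp>`
#' and `pc<k>` columns and metadata lines prefixed `#`. GWAS tables use the
#' conventional columns `snp, effect_allele, other_allele, eaf, beta, se,
#' pval, n` (plus `chrom`/`pos` when available).
#'
#' @param cohort An `aam_cohort` tibble.
#' @param path File path.
#' @return `write_*` return `path` invisibly; `read_*` return a tibble.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_cohort <- function(cohort, path) {
  flat <- cohort
  if ("dosages" %in% names(flat)) {
    G <- flat$dosages
    colnames(G) <- paste0("g_", colnames(G))
    flat$dosages <- NULL
    flat <- dplyr::bind_cols(flat, tibble::as_tibble(G))
  }
  if ("pcs" %in% names(flat)) {
    PC <- flat$pcs
    flat$pcs <- NULL
    flat <- dplyr::bind_cols(flat, tibble::as_tibble(PC))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# menarchemr cohort table; n=%d; written=%s",
                     nrow(flat), "menarchemr"), con)
  utils::write.table(flat, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' @param stats A GWAS summary tibble.
#' @rdname cohort_io
#' @export
write_gwas <- function(stats, path) {
  readr::write_tsv(stats, path)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_gwas <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval", "n")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    abort(paste0("GWAS table is missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  out
}
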