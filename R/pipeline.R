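# Configuration-driven end-to-end runs.

pipeline_config_keys <- c(
  "seed", "scenario", "m_imputations", "use_ipw", "steiger", "mvmr",
  "n_sim_presso", "n_boot_median", "write_cohort", "out_dir"
)

#' Default pipeline configuration
#'
#' @param seed Integer seed driving every stochastic stage (required for
#'   any run; no silent nondeterminism).
#' @param ... Overrides for top-level keys (`scenario` is itself a list of
#'   [sim_params()] arguments).
#' @return A named list validated by [run_pipeline()].
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    scenario = list(),
    m_imputations = 5,
    use_ipw = TRUE,
    steiger = TRUE,
    mvmr = TRUE,
    n_sim_presso = 1000,
    n_boot_median = 1000,
    write_cohort = TRUE
  )
  modifyList(cfg, list(...))
}

read_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  ok <- jsonlite::validate(txt)
  if (!ok) {
    msg <- attr(ok, "err")
    off <- regmatches(msg, regexpr("byte offset [0-9]+", msg))
    line_ref <- if (length(off)) {
      nb <- as.integer(sub("byte offset ", "", off))
      paste0(" (about line ",
             1L + lengths(regmatches(substr(txt, 1, nb),
                                     gregexpr("\n", substr(txt, 1, nb)))),
             ")")
    } else ""
    abort(paste0("Malformed config file '", path, "'", line_ref, ": ", msg))
  }
  jsonlite::fromJSON(txt, simplifyVector = TRUE)
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config(config)
  }
  unknown <- setdiff(names(config), pipeline_config_keys)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$seed)) {
    abort("Config must provide a `seed`; refusing a nondeterministic run.")
  }
  bad <- setdiff(names(config$scenario), names(formals(sim_params)))
  if (length(bad)) {
    abort(paste0("Unknown scenario key(s): ", paste(bad, collapse = ", ")))
  }
  modifyList(default_config(seed = config$seed), config)
}

# fit observational + 1SMR estimates for one imputed dataset
analyse_completed <- function(dat, score, weights = NULL) {
  covar_cols <- c("edu", "income", "parity", "mat_age", "confounder_u")
  cont_doms <- sub("^sym_", "", grep("^sym_", names(dat), value = TRUE))
  bin_doms <- sub("^diag_", "", grep("^diag_", names(dat), value = TRUE))
  x <- dat$exposure_x
  rows <- list()
  for (dom in cont_doms) {
    tr <- select_transform(dat[[paste0("sym_", dom)]])
    y <- standardize(tr$y)
    neg <- standardize(select_transform(dat[[paste0("neg_", dom)]])$y)
    dirn <- if (dom == "depression") "negative" else "two_sided"
    un <- fit_linear(y, x, weights = weights, direction = dirn,
                     outcome = dom)
    un$model <- "unadjusted"
    ad <- fit_linear(y, x, covars = cbind(dat[covar_cols], neg = neg),
                     weights = weights, direction = dirn, outcome = dom)
    ad$model <- "adjusted"
    mr <- mr_tsls(y, x, score, direction = dirn, outcome = dom)
    mr$model <- "1SMR"
    nc <- mr_tsls(neg, x, score, direction = dirn,
                  outcome = paste0(dom, "_negcontrol"))
    nc$model <- "1SMR-negcontrol"
    rows <- c(rows, list(un, ad, mr, nc))
  }
  for (dom in bin_doms) {
    case <- dat[[paste0("diag_", dom)]]
    dirn <- if (dom == "depression") "negative" else "two_sided"
    lbl <- paste0(dom, "_diag")
    un <- fit_logistic(case, x, weights = weights, direction = dirn,
                       outcome = lbl)
    un$model <- "unadjusted"
    ad <- fit_logistic(case, x, covars = dat[covar_cols],
                       weights = weights, direction = dirn, outcome = lbl)
    ad$model <- "adjusted"
    mr <- mr_tsls_logistic(case, x, score, direction = dirn, outcome = lbl)
    mr$model <- "1SMR"
    rows <- c(rows, list(un, ad, mr))
  }
  dplyr::bind_rows(lapply(rows, tidy))
}

pool_by_model <- function(stacked) {
  stacked |>
    dplyr::group_by(.data$outcome, .data$model) |>
    dplyr::group_modify(function(g, key) {
      pooled <- tibble::as_tibble(pool_rubin(g))
      pooled[setdiff(names(pooled), c("outcome", "model"))]
    }) |>
    dplyr::ungroup()
}

write_table <- function(tab, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full triangulation pipeline
#'
#' Generates the synthetic cohort and summary statistics, builds and audits
#' the instrument, imputes the censored exposure, fits observational and
#' one-sample MR models per imputation (pooling by Rubin's rules), runs the
#' two-sample sensitivity battery (optionally Steiger-filtered) and
#' multivariable MR, evaluates every registered hypothesis through the
#' decision engine, and writes all tables plus a manifest into a run
#' directory. Re-running with the same config reproduces every table
#' bit-for-bit.
#'
#' @param config A config list from [default_config()], or a path to a JSON
#'   config file.
#' @param dir Output run directory (created; must not already contain a
#'   manifest).
#' @return The run directory path, invisibly; the decision log is also
#'   returned as attribute `decisions`.
#' @export
run_pipeline <- function(config = default_config(), dir = tempfile("run")) {
  cfg <- validate_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  say("run started; seed=%d", as.integer(cfg$seed))

  params <- do.call(sim_params, modifyList(cfg$scenario,
                                           list(seed = cfg$seed)))
  cohort <- sim_cohort(params)
  say("cohort generated: n=%d, snps=%d", nrow(cohort), params$n_snps)

  # instrument: external weights are the panel's true effects measured with
  # GWAS noise (the exposure-side summary stats)
  pair <- sim_summary_pair(params)
  weights_snp <- pair$exposure_stats$beta
  grs <- compute_grs(cohort$dosages, weights_snp)
  nuisance <- cbind(stats::model.matrix(~ factor(cohort$batch))[, -1],
                    cohort$pcs)
  score <- residualize_score(grs, nuisance)
  audit <- audit_instrument(score, cohort$exposure_true,
                            cohort[c("edu", "income", "parity", "mat_age",
                                     "confounder_u")])
  say("instrument audit: r2=%.4f F=%.1f", audit$r2, audit$f_stat)

  # analysis sample: participants only, with IPW for attrition
  part <- cohort$participation
  ipw <- if (cfg$use_ipw) ipw_weights(cohort) else NULL
  ana <- cohort[part, ]
  ana_score <- score[part]
  w <- if (cfg$use_ipw) ipw$weights else NULL

  imp <- impute_censored(ana, m = cfg$m_imputations,
                         seed = child_seed(cfg$seed, 2L))
  say("imputed censored exposure: m=%d, censored=%d", imp$m,
      sum(ana$censored))

  stacked <- purrr::imap_dfr(imp$completed, function(dat, i) {
    res <- analyse_completed(dat, ana_score, weights = w)
    res$imp <- i
    res
  })
  results <- pool_by_model(stacked)

  # two-sample battery (depression symptoms), optionally Steiger-filtered
  battery <- mr_battery(pair, seed = child_seed(cfg$seed, 3L),
                        n_sim = cfg$n_sim_presso,
                        n_boot = cfg$n_boot_median)
  battery$variant <- "all SNPs"
  if (cfg$steiger) {
    filt <- steiger_filter(pair)
    b2 <- mr_battery(filt, seed = child_seed(cfg$seed, 4L),
                     n_sim = cfg$n_sim_presso,
                     n_boot = cfg$n_boot_median)
    b2$variant <- "steiger"
    battery <- dplyr::bind_rows(battery, b2)
    say("steiger filtering removed %d SNPs",
        sum(attr(filt, "removal_log")$removed))
  }

  mvmr_tab <- NULL
  if (cfg$mvmr) {
    mv <- sim_mvmr_stats(params)
    mvmr_tab <- tidy(mr_mvmr(mv$exposures, mv$outcome_stats))
  }

  # decision engine on the pooled per-SD estimates
  sd_x <- sd(imp$completed[[1]]$exposure_x)
  specs <- hypothesis_specs()
  model_for <- function(fam) if (fam == "mr") "1SMR" else "adjusted"
  decisions <- purrr::map_dfr(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    target <- if (sp$outcome_type == "diagnosis") {
      paste0(sp$domain, "_diag")
    } else sp$domain
    row <- results |>
      dplyr::filter(.data$outcome == target,
                    .data$model == model_for(sp$family))
    if (!nrow(row)) {
      return(tibble::tibble(id = sp$id, verdict = "not_evaluated"))
    }
    est <- new_estimate(row$estimate, row$se, row$n,
                        scale = row$scale, exposure_unit = "per_year",
                        method = row$method, outcome = row$outcome,
                        direction = sp$direction)
    est_sd <- rescale_per_year(est, sd_x)   # per-year -> per-SD
    nc <- NULL
    if (sp$requires_negcontrol) {
      ncrow <- results |>
        dplyr::filter(.data$outcome == paste0(sp$domain, "_negcontrol"),
                      .data$model == "1SMR-negcontrol")
      nc_est <- new_estimate(ncrow$estimate, ncrow$se, ncrow$n,
                             scale = ncrow$scale,
                             exposure_unit = "per_year",
                             direction = sp$direction)
      nc <- negative_control_test(est, nc_est)
    }
    decide_hypothesis(sp, est_sd, nc)
  })
  say("decisions: %s",
      paste(sprintf("%s=%s", decisions$id, decisions$verdict),
            collapse = " "))

  meta <- sprintf("seed=%d config_hash=%s", as.integer(cfg$seed),
                  rlang::hash(cfg))
  if (cfg$write_cohort) {
    write_cohort(cohort, file.path(dir, "cohort.tsv"))
  }
  write_gwas(pair$exposure_stats, file.path(dir, "gwas_exposure.tsv"))
  write_gwas(pair$outcome_stats, file.path(dir, "gwas_outcome.tsv"))
  write_table(results, file.path(dir, "results_models.tsv"), meta)
  write_table(battery |> dplyr::select(-dplyr::any_of("adjusted_for")),
              file.path(dir, "results_2smr.tsv"), meta)
  if (!is.null(mvmr_tab)) {
    write_table(mvmr_tab, file.path(dir, "results_mvmr.tsv"), meta)
  }
  write_table(decisions, file.path(dir, "decisions.tsv"), meta)
  write_table(audit$associations, file.path(dir, "instrument_audit.tsv"),
              c(meta, sprintf("r2=%.6f f=%.3f n=%d", audit$r2,
                              audit$f_stat, audit$n)))
  manifest <- list(
    package = "menarchemr",
    config = cfg, config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    n_cohort = nrow(cohort), n_participants = sum(part),
    instrument = list(r2 = audit$r2, f = audit$f_stat),
    tables = list.files(dir, pattern = "\\.tsv$")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(dir, "log.txt"))
  out <- invisible(dir)
  attr(out, "decisions") <- decisions
  out
}

#' Render a plain-text report for a pipeline run
#'
#' Reads the tables of a completed run directory and renders forest-style
#' text tables grouped by outcome domain (unadjusted, adjusted, one-sample
#' MR, negative control), the two-sample sensitivity battery, and the
#' decision log. Missing tables are listed, not fatal; numbers are taken
#' from the tables verbatim (no recomputation).
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return Character vector of report lines, invisibly; also printed.
#' @export
render_report <- function(run_dir) {
  fmt_est <- function(r) {
    sprintf("  %-18s %-16s % .3f [% .3f, % .3f]  p1=%.3f n=%d",
            r$outcome, r$model, r$estimate, r$ci_low, r$ci_high,
            r$p_one, r$n)
  }
  lines <- c("== menarchemr run report ==", paste("dir:", run_dir))
  missing <- character()
  path <- function(f) file.path(run_dir, f)

  if (file.exists(path("results_models.tsv"))) {
    res <- readr::read_tsv(path("results_models.tsv"), comment = "#",
                           show_col_types = FALSE)
    for (dom in unique(sub("_negcontrol$", "", res$outcome))) {
      sub <- res[sub("_negcontrol$", "", res$outcome) == dom, ]
      lines <- c(lines, paste0("-- domain: ", dom),
                 vapply(seq_len(nrow(sub)),
                        function(i) fmt_est(sub[i, ]), character(1)))
    }
  } else missing <- c(missing, "results_models.tsv")

  if (file.exists(path("results_2smr.tsv"))) {
    b <- readr::read_tsv(path("results_2smr.tsv"), comment = "#",
                         show_col_types = FALSE)
    lines <- c(lines, "-- two-sample MR battery",
               sprintf("  %-22s %-10s % .3f [% .3f, % .3f]",
                       b$method, b$variant, b$estimate, b$ci_low,
                       b$ci_high))
  } else missing <- c(missing, "results_2smr.tsv")

  if (file.exists(path("decisions.tsv"))) {
    d <- readr::read_tsv(path("decisions.tsv"), comment = "#",
                         show_col_types = FALSE)
    if (nrow(d) == 0) {
      lines <- c(lines, "no hypotheses evaluated")
    } else {
      lines <- c(lines, "-- decisions",
                 sprintf("  %-7s %s", d$id, d$verdict))
    }
  } else missing <- c(missing, "decisions.tsv")

  if (length(missing)) {
    lines <- c(lines, paste("missing tables:",
                            paste(missing, collapse = ", ")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
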