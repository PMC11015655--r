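---
title: "Triangulating the effect of pubertal timing on adolescent mental health: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Girls who reach menarche earlier report more depressive symptoms in
adolescence. Whether that association is causal is hard to settle
observationally: pubertal timing shares causes with adolescent mental health
(childhood body size prominently among them), and symptom reporting may
itself feed back on recall of pubertal milestones. menarchemr implements a
*triangulation* strategy: the same exposure-outcome question is asked of
several estimators with different, partially non-overlapping assumptions —
covariate-adjusted regression, one-sample Mendelian randomisation (MR),
two-sample summary-data MR with a battery of pleiotropy-robust estimators,
multivariable MR, and negative-control outcome analyses — and inference
criteria registered in advance combine the answers into explicit verdicts.

Because the motivating cohort's individual-level data are access-restricted,
the package is built around a synthetic cohort generator whose *stated
world* reproduces the study's structure. Every estimator is therefore
testable end to end against known truth, which is the package's main point:
a green test establishes that the estimator recovers the generator's truth
under the generator's assumptions — not that the substantive findings of any
particular cohort are correct.

## The generator's stated world

`sim_params()` fixes the world once; its defaults are the study's printed
calibration targets and are not tuned afterwards:

* n = 13,398 girls; age at menarche Normal(12.69, 1.18²) years.
* Right-censoring: menarche unobserved when it falls after the interview.
  The default `censor_age` is `12.69 + qnorm(1 - 0.0725) * 1.18 = 14.41` y,
  the unique value at which 7.25% of the stated exposure distribution is
  censored; it coincides with the ~14.4-year questionnaire return age.
* Instrument: 235 independent SNPs (`Binomial(2, maf)` loci, maf drawn from
  (0.1, 0.5)) whose per-allele effects are rescaled so the weighted allele
  score explains exactly `target_r2 = 0.069` of exposure variance in the
  population.
* Raw depressive symptom scores with mean 9.20, SD 6.56, generated as a
  shifted log-normal transform of a standard-normal latent
  (`raw = exp(mu + sigma z) - 1`, floored at 0). The shift-by-one form is
  chosen deliberately so that `log(y + 1)` *exactly* linearises the latent
  scale, forcing the transformation-selection logic to engage and making
  recovery of the latent-scale causal effect testable. Other symptom scales
  (anxiety 3.5/2.8, conduct 4.0/3.6, oppositionality 5.0/4.0, inattention
  8.0/6.0) are plausible short-questionnaire values chosen once; they are
  not printed targets.
* Binary diagnoses through a logistic link with the intercept solved
  numerically for the target prevalence (depression 5.2%; anxiety 4%,
  disruptive behaviour 1.5%, ADHD 3% — registry-style adolescent rates
  chosen once).
* Causal effects default to the calibration targets: −0.07/1.18 SD of
  depressive symptoms per year and log(0.74)/1.18 log-odds per year for
  depression diagnoses; zero for other domains.
* A single continuous confounder (childhood body size proxy) with effects
  −0.2 years on the exposure and +0.15 SD / +0.25 log-odds on outcomes;
  pre-pubertal negative-control scores (mean 5.71, SD 4.93) load on the
  confounder but never on the exposure.
* Participation is missing-at-random given baseline covariates
  (logistic model on the confounder, education and income, intercept 1.5,
  ~80% participation), which is exactly the identifying assumption of the
  inverse-probability weighting stage.
* Instrument-invalidity knobs: `invalid_fraction` of SNPs receive direct
  outcome effects α (balanced or directional via `alpha_mean`/`alpha_sd`);
  `phi` correlates the true score with the confounder.

What the generator does *not* emulate: linkage disequilibrium (loci are
independent, a post-clumping world; LD enters only through the clumping
module's explicit correlation-matrix interface), dosage-imputation
uncertainty, pedigree and population structure beyond the `phi` mechanism,
and item-level measurement of the symptom scales. Green tests therefore say
nothing about those features of real data.

## Estimators and numerical choices

**Observational models.** Symptom scales are transformed by whichever of
identity, `log(y+1)`, `sqrt(y)` minimises absolute skewness (absolute excess
kurtosis breaks ties), standardised, and regressed on the exposure with and
without covariates. Continuous covariates further than 3 SD from their mean
are set missing before fitting. With IPW weights (or on request) the
covariance is the HC1 sandwich with `n/(n-k)` scaling, computed in-package
because no sandwich-covariance package is assumed.

**One-sample MR.** Two-stage least squares with the residualised allele
score as instrument; the covariance uses residuals recomputed from the
observed exposure (not the first-stage fits), then the HC1 correction. For
diagnoses the second stage is logistic (two-stage predictor substitution;
residual inclusion available behind a flag, since predictor substitution is
the plain reading of "a logistic model in the second stage"). No covariates
enter MR models — adjusting an MR model can itself introduce bias — so the
instrument is cleaned beforehand by regressing out genotyping batch and 20
principal components.

**Two-sample MR.** Wald ratios with first-order standard errors
(second-order optional); fixed-effect IVW with multiplicative
random-effects SE inflation when Q/df > 1; MR-Egger after orienting
exposure betas positive, with multiplicative overdispersion scaling
`max(1, Q/(J-2))`; weighted median with linear interpolation across the
cumulative-weight midpoint and a seeded parametric bootstrap SE (1,000
draws); a contamination-mixture profile likelihood where each SNP
contributes the larger of a valid `N(theta, se²)` and an invalid
`N(0, psi²)` log-density, with `psi` defaulting to 1.5 × SD of the ratios
and the grid refined automatically so its spacing resolves a quarter of the
IVW standard error (otherwise sharply-peaked profiles can collapse the
confidence set onto single grid points); and an MR-PRESSO-style global test
whose observed statistic sums inverse-variance-weighted squared residuals
from leave-one-out IVW fits, with a parametric null (outcome betas redrawn
about leave-one-out predictions) and Bonferroni-flagged per-SNP outlier
tests. Multivariable MR regresses outcome betas on several exposures'
betas without intercept; conditional instrument strength for exposure k is
the weighted heterogeneity of its betas about their projection on the other
exposures, divided by J − K; residual heterogeneity is the modified Q with
J − K degrees of freedom, assuming non-overlapping exposure samples.

A deliberate scope note on robustness: the weighted median is consistent
when valid SNPs carry a majority of the weight, but under *one-sided*
directional pleiotropy it acquires a quantile-shift bias that does not
vanish however extreme the invalid ratios are. The recovery properties in
the test suite therefore use scattered (balanced) contamination, which is
the regime those estimators are designed for; directional pleiotropy is the
Egger intercept's job, and it is tested in that role.

**Steiger filtering.** Per-SNP variance explained is computed from
z-statistics, `r² = z²/(z² + n)`, which needs no allele frequencies; a SNP
is removed when it explains more variance in the outcome than the exposure,
ties retained. A stricter variant additionally requires Steiger's z-test
(Fisher transformation of the implied correlations) to be significant;
direction-only is the default because the registered analysis describes
only the direction criterion.

**Missing data.** Only the censored exposure is imputed — it is the one
variable with a hard registered constraint (imputed values not below 15
years) and a testable recovery metric against generator truth. Draws come
from a normal linear model fitted to observed girls, with parameter
uncertainty propagated (variance from its scaled inverse-chi-square
posterior, coefficients from their normal posterior) and inverse-CDF
sampling restricted to [15, ∞). Binary diagnoses are never imputed.
Estimates pool by Rubin's rules with the classical small-sample degrees of
freedom. Attrition weights are stabilised (`marginal / fitted`), truncated
at the 1st/99th percentiles by default, and reported beside a balance table
whose weighted and unweighted columns both compare participants with the
full invited cohort so they are directly comparable.

**Equivalence testing and decisions.** The registered smallest effects of
interest are Cohen's D values (0.23/0.25 for depression observational/MR,
0.22/0.20 for other domains). Conversion to the analysis scales uses
`d/sqrt(d² + 4)` for standardised betas and `d·pi/sqrt(3)` for log odds
ratios — both standard effect-size conversions, isolated in
`sesoi_to_scale()` because the study's own conversion appendix is not
available. Bounds are applied on the per-SD-of-exposure scale, matching the
standardised axes on which such results are plotted. Directional
hypotheses get a one-sided inferiority test, two-sided ones a TOST; the
verdict logic is: equivalence rejection dominates everything, otherwise a
significant NHST in the registered direction (plus a passing
negative-control comparison where required) supports the hypothesis,
otherwise the verdict is explicitly undecided.

**Negative controls.** With L the negative-control confidence bound
farthest from zero in the registered direction,
`z = (theta_hat − L)/se`, and the criterion passes when `p = 1 − Phi(z)` is
at least alpha — i.e. when we *fail* to reject that the main effect is at
least as extreme as the control bound. The registered text admits a second
reading ("upper bound" vs "lower 95% CI" for a negative effect); the
farthest-from-zero convention is canonical here and the comparison is
symmetric under sign conventions, so the alternative amounts to passing the
other bound's estimate.

**Power.** All power is Monte-Carlo at 1,000 replicates by default, with
the registered simulation scales (exposure Normal(12.69, 1.18²); outcome
mean 5.71, SD 4.93; D converted to r by `d/sqrt(d² + 4)` for linear tests
and to a per-SD log-OR by `d·pi/sqrt(3)` for logistic ones). Because the
registered mapping from D to the simulated 2SLS effect is ambiguous, both
readings (per-SD and per-year of exposure) are implemented and labelled;
`convention = "both"` emits one row per reading.

## Pipeline reproducibility

`run_pipeline()` refuses configs with unknown keys or without a seed; every
stochastic stage derives a child seed from the config seed, and re-running
the same config reproduces each emitted table bit-for-bit. The manifest
records the config hash and seeds. The imputation count defaults to 5 in
the pipeline config (20 in `impute_censored()` itself); simulation-heavy
tests run at reduced n and replicate counts to stay within test-time
budgets, and say so where they do.

## Known limitations

* The attrition model of the motivating study is not published in detail;
  the generator's coefficients are a stand-in and the IPW stage is
  validated against the generator's own missing-at-random mechanism only.
* Conditional F in multivariable MR assumes zero covariance between the
  exposure GWAS estimates (non-overlapping samples).
* No LD-aware MR, no within-family designs, no weak-instrument-robust
  (Anderson-Rubin) intervals.
* The categorical early/average/late exposure coding uses configurable
  quantile cut-points (default ±1 SD) because the registered cut-offs are
  in an unavailable appendix.
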