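#' Default lifestyle covariate distributions
#'
#' Named distribution descriptors whose defaults reproduce the first moments
#' reported for large postmenopausal breast-cancer cohorts: age ~ normal
#' (mean 66, SD 6.65) truncated to the 50-79 enrolment window (the location
#' is solved so the *truncated* mean is 66); dietary alcohol ~ zero-inflated
#' gamma (30% non-drinkers, overall mean 6.1 g/day, ~9.6% of women at or
#' above 18 g/day); BMI ~ normal(27.8, 5.4); binary covariates at the
#' reported cohort frequencies; hormone-use durations as never/short/medium/
#' long mixtures matching the reported category frequencies.
#'
#' Families: `normal` (optionally truncated, mean-preserving), `gamma`
#' (parameterised by mean and shape), `zi_gamma` (point mass at zero plus
#' gamma), `bernoulli`, `mixture_uniform` (weighted uniform components; a
#' component with `min == max` is a point mass), `constant`.
#'
#' @return Named list of distribution descriptors.
#' @export
default_covariate_specs <- function() {
  list(
    age = list(dist = "normal", mean = 66, sd = 6.65, min = 50, max = 79),
    education_high = list(dist = "bernoulli", p = 0.642),
    family_income_high = list(dist = "bernoulli", p = 0.531),
    famhist_diabetes = list(dist = "bernoulli", p = 0.280),
    famhist_breast_ca = list(dist = "bernoulli", p = 0.189),
    depressive_symptom = list(dist = "zi_gamma", p_zero = 0.8,
                              mean = 0.135, shape = 0.5),
    alcohol_g_day = list(dist = "zi_gamma", p_zero = 0.3,
                         mean = 6.1 / 0.7, shape = 0.8),
    pct_protein = list(dist = "normal", mean = 16.67, sd = 3.06),
    pct_sfa = list(dist = "normal", mean = 11.34, sd = 2.9, min = 2),
    pct_mfa = list(dist = "normal", mean = 12.70, sd = 3.26, min = 2),
    pct_pfa = list(dist = "normal", mean = 6.82, sd = 2.08, min = 0.5),
    met_h_wk = list(dist = "gamma", mean = 11, shape = 1),
    cigarettes_day = list(dist = "mixture_uniform", components = list(
      list(weight = 0.563, min = 0, max = 15),
      list(weight = 0.437, min = 15, max = 40)
    )),
    bmi = list(dist = "normal", mean = 27.78, sd = 5.4, min = 15, max = 60),
    waist_cm = list(dist = "normal", mean = 86.8, sd = 12.8, min = 50),
    hip_cm = list(dist = "normal", mean = 106.5, sd = 11.1, min = 60),
    whr = list(dist = "normal", mean = 0.813, sd = 0.073,
               min = 0.55, max = 1.2),
    age_menarche = list(dist = "normal", mean = 13, sd = 1.44,
                        min = 8, max = 18),
    age_menopause = list(dist = "normal", mean = 48, sd = 6.2,
                         min = 30, max = 60),
    hysterectomy = list(dist = "bernoulli", p = 0.360),
    oc_years = list(dist = "normal", mean = 5.67, sd = 3.27, min = 0),
    e_only_years = list(dist = "mixture_uniform", components = list(
      list(weight = 0.695, min = 0, max = 0),
      list(weight = 0.139, min = 0.5, max = 5),
      list(weight = 0.053, min = 5, max = 10),
      list(weight = 0.113, min = 10, max = 25)
    )),
    ep_years = list(dist = "mixture_uniform", components = list(
      list(weight = 0.821, min = 0, max = 0),
      list(weight = 0.097, min = 0.5, max = 5),
      list(weight = 0.043, min = 5, max = 10),
      list(weight = 0.039, min = 10, max = 25)
    ))
  )
}

#' Specify a synthetic cohort
#'
#' Collects everything the generator needs: cohort size, per-SNP minor
#' allele frequencies, covariate distribution descriptors, planted
#' proportional-hazards effects (main-effect log hazard ratios, optional
#' binary risk-genotype indicator terms, and pairwise interaction terms), a
#' constant baseline hazard (calibrated to a target event fraction when not
#' given), and the administrative censoring window. Defaults emulate a
#' cohort of 10,179 postmenopausal women with 156 SNPs in Hardy-Weinberg
#' equilibrium followed for a mean of 16 years, with 537 incident breast
#' cancers (event fraction 5.28%).
#'
#' @param n Number of subjects (>= 2).
#' @param mafs Per-SNP minor-allele frequencies in (0, 0.5]; default an
#'   evenly spaced ladder over 0.05-0.5 of length `n_snps`.
#' @param n_snps Number of SNPs when `mafs` is not given.
#' @param covariate_specs Named distribution descriptors; see
#'   [default_covariate_specs()].
#' @param log_hr Named numeric of log hazard ratios. Names refer to design
#'   columns: covariates, SNP dosage columns (additive coding), or indicator
#'   terms declared via `indicators`.
#' @param indicators Named list of `list(var =, in_set =)` entries; each
#'   adds a binary design column equal to 1 when `var` takes a value in
#'   `in_set` (used to plant risk-genotype rather than additive effects).
#' @param interactions List of `list(a =, b =, log_hr =)` product terms.
#' @param baseline_hazard Constant per-year baseline hazard; `NULL` (the
#'   default) calibrates it to `event_target` by the closed-form
#'   exponential-censoring relation.
#' @param followup Administrative censoring window `c(min, max)` in years,
#'   drawn uniformly; the default 12-20 gives a mean 16-year follow-up.
#' @param event_target Target marginal event fraction used when
#'   `baseline_hazard` is `NULL`.
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(n = 10179, mafs = NULL, n_snps = 156,
                     covariate_specs = default_covariate_specs(),
                     log_hr = NULL, indicators = NULL, interactions = NULL,
                     baseline_hazard = NULL, followup = c(12, 20),
                     event_target = 537 / 10179) {
  if (n < 2) abort("n must be at least 2", class = "riskforest_config_error")
  if (is.null(mafs))
    mafs <- setNames(round(seq(0.05, 0.5, length.out = n_snps), 4),
                     sprintf("SNP_%03d", seq_len(n_snps)))
  if (any(mafs <= 0 | mafs > 0.5))
    abort("minor allele frequencies must lie in (0, 0.5]",
          class = "riskforest_config_error")
  if (is.null(names(mafs)))
    names(mafs) <- sprintf("SNP_%03d", seq_along(mafs))
  if (!is.null(baseline_hazard) && baseline_hazard <= 0)
    abort("baseline hazard must be positive",
          class = "riskforest_config_error")
  stopifnot(length(followup) == 2, followup[1] > 0,
            followup[2] >= followup[1])
  structure(
    list(n = as.integer(n), mafs = mafs, covariate_specs = covariate_specs,
         log_hr = log_hr, indicators = indicators,
         interactions = interactions, baseline_hazard = baseline_hazard,
         followup = followup, event_target = event_target),
    class = "sim_spec"
  )
}
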