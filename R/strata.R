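#' Define an obesity-stratum split
#'
#' A stratum specification names a covariate, a cutoff, and which comparison
#' defines the first ("low"-labelled) stratum. The conventions mirror the
#' obesity strata used in gene-lifestyle breast-cancer profiling: BMI < 30
#' vs >= 30 kg/m2, waist <= 88 vs > 88 cm, waist-to-hip ratio <= 0.85
#' vs above, physical activity >= 10 vs < 10 MET-h/week, and % calories from
#' saturated fat < 9 vs >= 9. Note the mixed boundary rules (`<` vs `<=` vs
#' `>=`): they are fixed here so downstream code cannot drift.
#'
#' @param variable Covariate name.
#' @param cutoff Finite numeric cutoff.
#' @param side Comparison defining the low stratum: `"lt"` (`x < cutoff`),
#'   `"le"` (`x <= cutoff`) or `"ge"` (`x >= cutoff`).
#' @param label Optional display label.
#' @return A `stratum_spec` object.
#' @export
stratum_spec <- function(variable, cutoff, side = c("lt", "le", "ge"),
                         label = NULL) {
  side <- match.arg(side)
  if (!is.finite(cutoff))
    abort("stratum cutoff must be finite", class = "riskforest_config_error")
  structure(
    list(variable = variable, cutoff = cutoff, side = side,
         label = label %||% variable),
    class = "stratum_spec"
  )
}

#' The five standard obesity strata
#' @return A named list of [stratum_spec()] objects (bmi, waist, whr, met,
#'   sfa).
#' @export
default_strata <- function() {
  list(
    bmi = stratum_spec("bmi", 30, "lt", "BMI (kg/m2)"),
    waist = stratum_spec("waist_cm", 88, "le", "Waist circumference (cm)"),
    whr = stratum_spec("whr", 0.85, "le", "Waist-to-hip ratio"),
    met = stratum_spec("met_h_wk", 10, "ge", "Physical activity (MET-h/wk)"),
    sfa = stratum_spec("pct_sfa", 9, "lt", "% calories from SFA")
  )
}

#' Split a cohort into two strata
#'
#' Partitions the cohort by the stratum cutoff; every subject lands in
#' exactly one stratum (no drops, no duplicates).
#'
#' @param x A [cohort()].
#' @param spec A [stratum_spec()].
#' @return A named list of two cohorts, `low` and `high`.
#' @export
stratify <- function(x, spec) {
  stopifnot(inherits(x, "cohort"), inherits(spec, "stratum_spec"))
  v <- x$data[[spec$variable]]
  if (is.null(v))
    abort(paste0("stratum variable '", spec$variable, "' not in covariates"),
          class = "riskforest_config_error")
  if (anyNA(v))
    abort(paste0("stratum variable '", spec$variable, "' has missing values"),
          class = "riskforest_validation_error")
  low <- switch(spec$side,
    lt = v < spec$cutoff,
    le = v <= spec$cutoff,
    ge = v >= spec$cutoff
  )
  list(low = subset_cohort(x, which(low)),
       high = subset_cohort(x, which(!low)))
}
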