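#' Cox proportional-hazards fit with report-ready output
#'
#' Fits a proportional-hazards model for a set of focal terms with
#' adjustment covariates, maximizing the partial likelihood (Efron tie
#' handling by default). [tidy()] returns hazard ratios with Wald 95%
#' confidence intervals, raw and Benjamini-Hochberg-adjusted p-values (the
#' focal terms of one fit form one adjustment family); [glance()] reports
#' fit-level summaries; [schoenfeld_check()] runs the proportional-hazards
#' diagnostics.
#'
#' @param data Modelling frame.
#' @param terms Focal model terms (column names, or formula fragments such
#'   as `"factor(C)"`).
#' @param covariates Adjustment covariates.
#' @param ties `"efron"` or `"breslow"`.
#' @param time,event Column names.
#' @return A `cox_result` wrapping the `survival::coxph` fit.
#' @export
cox_fit <- function(data, terms, covariates = NULL,
                    ties = c("efron", "breslow"),
                    time = "time_years", event = "event") {
  ties <- match.arg(ties)
  if (sum(data[[event]]) < 2)
    abort("fewer than 2 events", class = "riskforest_fit_error")
  rhs <- paste(c(terms, covariates), collapse = " + ")
  f <- as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ", rhs))
  fit <- tryCatch(
    survival::coxph(f, data = data, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        abort(paste0("Cox fit unstable (monotone likelihood?): ",
                     conditionMessage(w)),
              class = "riskforest_fit_error")
      }
      suppressWarnings(survival::coxph(f, data = data, ties = ties))
    }
  )
  if (any(is.na(coef(fit))))
    abort("Cox design is rank-deficient (inestimable term)",
          class = "riskforest_fit_error")
  structure(
    list(fit = fit, terms = terms, covariates = covariates,
         data = data, time = time, event = event),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

focal_rows <- function(x) {
  cn <- names(coef(x$fit))
  # coefficients whose name starts with any focal term expression
  keep <- rep(FALSE, length(cn))
  for (tm in x$terms) {
    base <- gsub("[`]", "", tm)
    keep <- keep | startsWith(cn, base) |
      startsWith(cn, gsub("^factor\\((.*)\\)$", "\\1", base))
  }
  keep
}

#' @exportS3Method generics::tidy
tidy.cox_result <- function(x, conf_level = 0.95, adjust = TRUE,
                            focal_only = FALSE, ...) {
  fit <- x$fit
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    term = names(b),
    hr = unname(exp(b)),
    conf.low = unname(exp(b - z * se)),
    conf.high = unname(exp(b + z * se)),
    p.value = unname(pchisq((b / se)^2, 1, lower.tail = FALSE))
  )
  keep <- focal_rows(x)
  if (adjust) {
    out$p.adjusted <- NA_real_
    out$p.adjusted[keep] <- bh_adjust(out$p.value[keep])
  }
  if (focal_only) out <- out[keep, ]
  out
}

#' @exportS3Method generics::glance
glance.cox_result <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    n = s$n, n_events = s$nevent,
    concordance = unname(s$concordance[1]),
    likelihood_ratio_p = unname(s$logtest["pvalue"])
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone-enforced), applied to
#' all hazard ratios reported within one table as a single family.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Proportional-hazards diagnostics via Schoenfeld residuals
#'
#' For each model term, the correlation `rho` between the scaled Schoenfeld
#' residuals and the rank of the event times, with the corresponding
#' chi-square test p-value (Grambsch-Therneau, rank transform). The
#' residual-by-time data are returned for plotting.
#'
#' @param x A [cox_fit()] result.
#' @return List with `table` (term, rho, p) and `residuals` (long tibble of
#'   scaled residuals against event time).
#' @export
schoenfeld_check <- function(x) {
  zp <- survival::cox.zph(x$fit, transform = "rank", terms = FALSE)
  terms <- setdiff(rownames(zp$table), "GLOBAL")
  rho <- vapply(seq_along(terms), function(j)
    cor(rank(zp$time), zp$y[, j]), numeric(1))
  tab <- tibble::tibble(
    term = terms, rho = rho,
    p.value = zp$table[terms, "p"]
  )
  resid_long <- tibble::as_tibble(as.data.frame(zp$y)) %>%
    dplyr::mutate(time = zp$time) %>%
    tidyr::pivot_longer(-"time", names_to = "term",
                        values_to = "residual")
  list(table = tab, residuals = resid_long)
}

#' Wald trend test across an ordinal risk score
#'
#' Enters the score with linear coding (0, 1, 2, ...) in the adjusted model
#' and reports the Wald p-value of its coefficient.
#'
#' @param data Modelling frame.
#' @param score Ordinal score column name.
#' @param covariates Adjustment covariates.
#' @param time,event Column names.
#' @return P-value for linear trend.
#' @export
trend_test <- function(data, score, covariates = NULL,
                       time = "time_years", event = "event") {
  if (length(unique(data[[score]])) < 2)
    abort("trend test needs at least 2 score levels",
          class = "riskforest_undefined_error")
  fit <- cox_fit(data, score, covariates, time = time, event = event)
  td <- tidy(fit, adjust = FALSE)
  unname(td$p.value[td$term == score][1])
}

#' Joint-effect table of a risk score by an exposure stratifier
#'
#' Hazard ratios for each level of the combined risk score, overall and
#' within the two levels of a binary exposure stratifier (e.g. dietary
#' alcohol below/at-or-above 18 g/day), each against the lowest-risk
#' reference cell of its column, with cell counts, Benjamini-Hochberg
#' adjustment across all estimated rows of the table, and a linear trend
#' test across score levels. Variables under stratification or joint
#' testing must not appear among the covariates. Score levels without
#' events yield `NA` estimates with counts still shown.
#'
#' @param data Modelling frame.
#' @param score Risk-score column (ordinal, lowest level = reference).
#' @param stratifier Binary exposure column (0/1).
#' @param covariates Adjustment covariates.
#' @param time,event Column names.
#' @return A `joint_effect` tibble: `stratum` (`total`/`low`/`high`),
#'   `level`, `n`, `hr`, `conf.low`, `conf.high`, `p.value`, `p.adjusted`,
#'   with the trend p-value in `attr(, "p_trend")`.
#' @export
joint_effect_table <- function(data, score, stratifier, covariates = NULL,
                               time = "time_years", event = "event") {
  assert_binary(data[[stratifier]], "stratifier")
  if (any(c(score, stratifier) %in% covariates))
    abort("stratified/jointly tested variables cannot also be covariates",
          class = "riskforest_config_error")
  levels <- sort(unique(data[[score]]))
  fit_column <- function(df, label) {
    counts <- purrr::map_int(levels, ~ sum(df[[score]] == .x))
    est <- tibble::tibble(
      stratum = label, level = levels, n = counts,
      hr = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
      p.value = NA_real_
    )
    est$hr[1] <- 1  # reference cell by construction
    fit <- tryCatch(
      cox_fit(df, paste0("factor(", score, ")"), covariates,
              time = time, event = event),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      td <- tidy(fit, adjust = FALSE, focal_only = TRUE)
      for (i in seq_along(levels[-1])) {
        nm <- paste0("factor(", score, ")", levels[i + 1])
        row <- td[td$term == nm, ]
        if (nrow(row) == 1) {
          est[i + 1, c("hr", "conf.low", "conf.high", "p.value")] <-
            row[c("hr", "conf.low", "conf.high", "p.value")]
        }
      }
    }
    est
  }
  out <- dplyr::bind_rows(
    fit_column(data, "total"),
    fit_column(data[data[[stratifier]] == 0, ], "low"),
    fit_column(data[data[[stratifier]] == 1, ], "high")
  )
  out$p.adjusted <- NA_real_
  est_rows <- !is.na(out$p.value)
  out$p.adjusted[est_rows] <- bh_adjust(out$p.value[est_rows])
  p_trend <- trend_test(data, score, covariates, time = time, event = event)
  structure(out, p_trend = p_trend,
            class = c("joint_effect", class(out)))
}

#' Multiplicative and additive gene-environment interaction
#'
#' Fits the joint model with both binary factors and their product. The
#' multiplicative interaction is the product-term hazard ratio with its
#' Wald p; the additive interaction is the relative excess risk due to
#' interaction, `RERI = HR11 - HR10 - HR01 + 1`, with a delta-method
#' confidence interval (RERI = 0 under exact additivity of risks).
#'
#' @param data Modelling frame.
#' @param g,e Binary factor columns (genotype score, exposure).
#' @param covariates Adjustment covariates.
#' @param conf_level Confidence level for the RERI interval.
#' @param time,event Column names.
#' @return Tibble with the product-term HR, its p-value, and RERI with CI.
#' @export
interaction_test <- function(data, g, e, covariates = NULL,
                             conf_level = 0.95,
                             time = "time_years", event = "event") {
  for (v in c(g, e)) {
    x <- data[[v]]
    assert_binary(x, v)
    if (length(unique(x)) < 2)
      abort(paste0("factor '", v, "' is constant"),
            class = "riskforest_config_error")
  }
  term <- paste0(g, " * ", e)
  fit <- cox_fit(data, term, covariates, time = time, event = event)
  b <- coef(fit$fit)
  V <- vcov(fit$fit)
  nm_g <- g; nm_e <- e
  nm_ge <- intersect(c(paste0(g, ":", e), paste0(e, ":", g)), names(b))
  b1 <- b[nm_g]; b2 <- b[nm_e]; b3 <- b[nm_ge]
  hr11 <- exp(b1 + b2 + b3); hr10 <- exp(b1); hr01 <- exp(b2)
  reri <- unname(hr11 - hr10 - hr01 + 1)
  grad <- numeric(length(b))
  names(grad) <- names(b)
  grad[nm_g] <- hr11 - hr10
  grad[nm_e] <- hr11 - hr01
  grad[nm_ge] <- hr11
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  z <- qnorm(1 - (1 - conf_level) / 2)
  se_b3 <- sqrt(V[nm_ge, nm_ge])
  tibble::tibble(
    product_hr = unname(exp(b3)),
    product_conf.low = unname(exp(b3 - z * se_b3)),
    product_conf.high = unname(exp(b3 + z * se_b3)),
    product_p = unname(pchisq((b3 / se_b3)^2, 1, lower.tail = FALSE)),
    reri = reri,
    reri_conf.low = reri - z * se,
    reri_conf.high = reri + z * se
  )
}
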