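#' Count risk genotypes and binarize
#'
#' Each SNP contributes when the subject's dosage falls in that SNP's
#' declared risk-genotype set (e.g. heterozygote plus minor homozygote =
#' dosages 1 and 2, or major homozygote alone = dosage 0). The binary
#' genotype indicator `G` is 1 when the count reaches `g_threshold` —
#' by default the full panel, matching codings where only carriers of
#' every risk genotype are high-risk.
#'
#' @param data Frame containing the SNP dosage columns.
#' @param snp_risk Named list: SNP column -> vector of risk dosages.
#' @param g_threshold Count needed for `G = 1` (default: all SNPs in the
#'   coding).
#' @return Tibble with `n_risk_genotypes` and `G`.
#' @export
assign_risk_genotype <- function(data, snp_risk,
                                 g_threshold = length(snp_risk)) {
  stopifnot(length(snp_risk) > 0)
  ind <- vapply(names(snp_risk), function(s) {
    x <- data[[s]]
    if (is.null(x))
      abort(paste0("SNP '", s, "' not found"),
            class = "riskforest_config_error")
    as.numeric(x %in% snp_risk[[s]])
  }, numeric(nrow(data)))
  count <- as.integer(rowSums(ind))
  tibble::tibble(n_risk_genotypes = count,
                 G = as.integer(count >= g_threshold))
}

#' The four canonical high-risk lifestyle rules
#'
#' Alcohol >= 18 g/day, estrogen-plus-progestin use >= 10 years, past oral
#' contraceptive use < 5 years, BMI >= 30 kg/m2.
#'
#' @return Tibble with `variable`, `cutoff`, `direction`.
#' @export
default_lifestyle_risk <- function() {
  tibble::tibble(
    variable = c("alcohol_g_day", "ep_years", "oc_years", "bmi"),
    cutoff = c(18, 10, 5, 30),
    direction = c("ge", "ge", "lt", "ge")
  )
}

#' Count risk lifestyles and code them
#'
#' Counts how many declared risk behaviors a subject carries (each rule is a
#' cutoff plus a direction: `"ge"`, `"gt"`, `"le"`, `"lt"`), then codes the
#' behavioral factor `B` either binarized (`b_levels = 2`: 0 = none, 1 = one
#' or more) or on three levels (`b_levels = 3`: 0, 1, 2 = two or more).
#'
#' @param data Frame with the lifestyle columns.
#' @param lifestyle_risk Tibble with `variable`, `cutoff`, `direction`
#'   (default [default_lifestyle_risk()]).
#' @param b_levels 2 or 3.
#' @return Tibble with `n_risk_lifestyles` and `B`.
#' @export
assign_risk_lifestyle <- function(data,
                                  lifestyle_risk = default_lifestyle_risk(),
                                  b_levels = 2) {
  stopifnot(b_levels %in% c(2, 3))
  ind <- vapply(seq_len(nrow(lifestyle_risk)), function(i) {
    v <- lifestyle_risk$variable[i]
    x <- data[[v]]
    if (is.null(x))
      abort(paste0("lifestyle '", v, "' not found"),
            class = "riskforest_config_error")
    cut <- lifestyle_risk$cutoff[i]
    switch(lifestyle_risk$direction[i],
           ge = as.numeric(x >= cut), gt = as.numeric(x > cut),
           le = as.numeric(x <= cut), lt = as.numeric(x < cut),
           abort("direction must be ge/gt/le/lt",
                 class = "riskforest_config_error"))
  }, numeric(nrow(data)))
  count <- as.integer(rowSums(ind))
  B <- if (b_levels == 2) as.integer(count >= 1L) else pmin(count, 2L)
  tibble::tibble(n_risk_lifestyles = count, B = B)
}

#' Combined gene-lifestyle risk score
#'
#' `C = G + B` after binarizing both components: 0 = low risk for genotypes
#' and behaviors, 1 = high risk for either, 2 = high risk for both.
#'
#' @param G Binary genotype risk indicator.
#' @param B Behavioral risk code (0/1 or 0/1/2; binarized here).
#' @return Integer score in \{0, 1, 2\}.
#' @export
combine_gene_lifestyle <- function(G, B) {
  assert_binary(G, "G")
  as.integer(G + pmin(as.integer(B), 1L))
}

#' Derive risk-genotype sets from cumulative incidence
#'
#' For each SNP, labels as risk genotypes the dosage levels whose
#' Nelson-Aalen cumulative breast-cancer incidence at the end of follow-up
#' exceeds the pooled incidence — a data-driven counterpart of reading
#' high-risk genotypes off predicted cumulative-incidence curves. Levels
#' carried by fewer than `min_n` subjects are merged with the nearest
#' larger level.
#'
#' @param data Modelling frame with dosage columns.
#' @param snps SNP columns to code.
#' @param min_n Minimum subjects per dosage level.
#' @param time,event Column names.
#' @return Named list suitable for [assign_risk_genotype()].
#' @export
derive_risk_coding <- function(data, snps, min_n = 30,
                               time = "time_years", event = "event") {
  tt <- data[[time]]; ev <- data[[event]]
  pooled <- na_tail_incidence(tt, ev)
  out <- list()
  for (s in snps) {
    g <- data[[s]]
    levels <- sort(unique(g))
    grp <- g
    # merge sparse dosage levels downward into the carrier group
    for (l in levels) if (sum(g == l) < min_n && l > 0) grp[g == l] <- 1
    risk <- c()
    for (l in sort(unique(grp))) {
      idx <- grp == l
      if (na_tail_incidence(tt[idx], ev[idx]) > pooled)
        risk <- c(risk, levels[levels >= l & levels <= max(g[idx])])
    }
    out[[s]] <- unique(if (length(risk)) risk else max(levels))
  }
  out
}

na_tail_incidence <- function(time, event) {
  if (sum(event) == 0) return(0)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  1 - exp(-max(sf$cumhaz))
}
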