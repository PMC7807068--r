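#' Genotype quality-control filter
#'
#' Removes SNPs with a missing-call rate at or above `max_missing_rate` or an
#' exact Hardy-Weinberg equilibrium p-value below `min_hwe_p` (computed on
#' the non-missing calls). These are the standard per-SNP array QC rules for
#' association cohorts: SNPs are kept when the missing-call rate is below 2%
#' and HWE p >= 1e-4.
#'
#' @param x A [cohort()].
#' @param max_missing_rate SNPs with missing rate `>=` this are removed.
#' @param min_hwe_p SNPs with exact HWE p `<` this are removed.
#' @return The filtered cohort. The per-SNP report (missing rate, HWE p,
#'   removal flag and reason) is attached as attribute `"qc_report"` and
#'   available via [qc_report()].
#' @export
qc_filter <- function(x, max_missing_rate = 0.02, min_hwe_p = 1e-4) {
  stopifnot(inherits(x, "cohort"))
  if (max_missing_rate <= 0 || max_missing_rate >= 1 ||
      min_hwe_p <= 0 || min_hwe_p >= 1)
    abort("QC thresholds must lie in (0, 1)",
          class = "riskforest_config_error")
  g <- x$genotypes
  miss <- colMeans(is.na(g))
  counts <- vapply(seq_len(ncol(g)), function(j) {
    gj <- g[, j]
    c(sum(gj == 0L, na.rm = TRUE), sum(gj == 1L, na.rm = TRUE),
      sum(gj == 2L, na.rm = TRUE))
  }, numeric(3))
  hwe_p <- hwe_exact_test(counts[1, ], counts[2, ], counts[3, ])
  fail_miss <- miss >= max_missing_rate
  fail_hwe <- hwe_p < min_hwe_p
  removed <- fail_miss | fail_hwe
  reason <- dplyr::case_when(
    fail_miss & fail_hwe ~ "missing_rate;hwe",
    fail_miss ~ "missing_rate",
    fail_hwe ~ "hwe",
    TRUE ~ NA_character_
  )
  report <- tibble::tibble(
    snp_id = colnames(g), missing_rate = miss, hwe_p = hwe_p,
    removed = removed, reason = reason
  )
  if (all(removed))
    warn("all SNPs removed by QC")
  out <- x
  out$genotypes <- g[, !removed, drop = FALSE]
  out$snp_info <- out$snp_info[!removed, , drop = FALSE]
  attr(out, "qc_report") <- report
  out
}

#' Retrieve the QC report attached by [qc_filter()]
#' @param x A cohort returned by [qc_filter()].
#' @return A tibble with one row per SNP tested.
#' @export
qc_report <- function(x) attr(x, "qc_report")

#' Impute missing genotype calls to the per-SNP mode
#'
#' Mode imputation preserves the marginal genotype distribution at the
#' cohort sizes this package targets; ties resolve to the smaller dosage.
#'
#' @param g Genotype dosage matrix with `NA` for missing calls.
#' @return The matrix with missing entries filled in.
#' @export
impute_genotypes_mode <- function(g) {
  for (j in seq_len(ncol(g))) {
    nas <- is.na(g[, j])
    if (!any(nas)) next
    tab <- tabulate(g[!nas, j] + 1L, nbins = 3L)
    g[nas, j] <- which.max(tab) - 1L
  }
  g
}

#' Per-SNP minor allele frequency
#' @param x A [cohort()] or genotype matrix.
#' @return Named numeric vector of allele frequencies of the counted allele
#'   (missing calls excluded pairwise).
#' @export
minor_allele_freq <- function(x) {
  g <- if (inherits(x, "cohort")) x$genotypes else x
  colMeans(g, na.rm = TRUE) / 2
}
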