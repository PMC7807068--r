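#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test for deviation from Hardy-Weinberg genotype
#' proportions, based on the conditional distribution of the heterozygote
#' count given the observed allele counts (Levene/Haldane distribution). The
#' p-value is the summed probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed
#' configuration, the usual two-sided convention for this test.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (major homozygote, heterozygote,
#'   minor homozygote). Vectors are recycled elementwise.
#' @return Exact p-value(s) in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)   # perfectly HWE-proportioned
#' hwe_exact_test(40, 20, 40)   # strong heterozygote deficit
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  ln <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(as.integer(n_AA), ln)
  n_Aa <- rep_len(as.integer(n_Aa), ln)
  n_aa <- rep_len(as.integer(n_aa), ln)
  vapply(seq_len(ln), function(i) {
    hwe_exact_one(n_AA[i], n_Aa[i], n_aa[i])
  }, numeric(1))
}

hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) || anyNA(c(n_AA, n_Aa, n_aa)))
    abort("genotype counts must be nonnegative",
          class = "riskforest_validation_error")
  n <- n_AA + n_Aa + n_aa
  if (n == 0)
    abort("all genotype counts are zero; HWE test undefined",
          class = "riskforest_undefined_error")
  # rare-allele count; symmetric in allele labels
  n_rare <- 2L * min(n_AA, n_aa) + n_Aa
  if (n_rare == 0L) return(1)
  hets <- seq.int(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  # log conditional probability up to a constant:
  #   P(h) propto 2^h / (h! * n_rr! * n_cc!) with
  #   n_rr = (n_rare - h)/2 rare homozygotes, n_cc = n - n_rr - h
  n_rr <- (n_rare - hets) / 2
  n_cc <- n - n_rr - hets
  lp <- hets * log(2) - lfactorial(hets) - lfactorial(n_rr) - lfactorial(n_cc)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}
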