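# shared fixture builders (all data generated in code)

# tiny three-subject cohort files on disk, returns the directory
write_tiny_cohort_files <- function(dir = tempfile("cohort")) {
  dir.create(dir)
  readr::write_tsv(
    tibble::tibble(subject_id = c("a", "b", "c"),
                   rs1 = c(0L, 1L, 2L), rs2 = c(NA, 0L, 1L)),
    file.path(dir, "genotypes.tsv"))
  readr::write_tsv(
    tibble::tibble(subject_id = c("a", "b", "c"),
                   bmi = c(24.5, 31.0, 28.2), smoker = c("no", "yes", "no")),
    file.path(dir, "covariates.tsv"))
  readr::write_tsv(
    tibble::tibble(subject_id = c("a", "b", "c"),
                   time_years = c(4.2, 10.0, 16.5), event = c(1L, 0L, 1L)),
    file.path(dir, "outcome.tsv"))
  dir
}

# small simulated modelling frame with optional planted effects
sim_frame <- function(n = 500, n_snps = 5, log_hr = NULL, seed = 1,
                      event_target = 537 / 10179, mafs = NULL,
                      interactions = NULL, indicators = NULL) {
  mafs <- mafs %||% stats::setNames(rep(0.3, n_snps),
                                    sprintf("SNP_%03d", seq_len(n_snps)))
  sp <- sim_spec(
    n = n, mafs = mafs,
    covariate_specs = list(age = list(dist = "normal", mean = 66, sd = 6.65)),
    log_hr = log_hr, interactions = interactions, indicators = indicators,
    event_target = event_target
  )
  as_analysis_frame(simulate_cohort(sp, seed = seed))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# independent two-sample log-rank statistic from the 2x2 tables at each
# distinct event time (oracle; kept free of package internals)
logrank_oracle <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(group) == length(time))
  U <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    Y <- sum(at_risk); Y1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    U <- U + d1 - d * Y1 / Y
    if (Y > 1) V <- V + d * (Y1 / Y) * (1 - Y1 / Y) * (Y - d) / (Y - 1)
  }
  U / sqrt(V)
}

# brute-force Harrell concordance by pair enumeration (oracle)
cindex_oracle <- function(time, event, risk) {
  conc <- 0; np <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1 || is.na(risk[i])) next
    for (j in seq_len(n)) {
      if (j == i || is.na(risk[j])) next
      usable <- time[i] < time[j] || (time[i] == time[j] && event[j] == 0)
      if (!usable) next
      np <- np + 1
      conc <- conc + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    }
  }
  if (np == 0) return(NA_real_)
  conc / np
}

# exact HWE p by full enumeration over heterozygote counts (oracle)
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  n_a <- min(n_a, 2 * n - n_a)
  if (n_a == 0) return(1)
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  # P(h | allele counts) proportional to 2^h / (h! nrr! ncc!)
  lp <- vapply(hets, function(h) {
    nrr <- (n_a - h) / 2
    ncc <- n - nrr - h
    h * log(2) - lfactorial(h) - lfactorial(nrr) - lfactorial(ncc)
  }, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Nelson-Aalen cumulative hazard evaluated at given grid times (oracle)
nelson_aalen_oracle <- function(time, event, grid) {
  H <- 0; out <- numeric(length(grid))
  ev_times <- sort(unique(time[event == 1]))
  for (g in seq_along(grid)) {
    H <- 0
    for (t in ev_times[ev_times <= grid[g]]) {
      H <- H + sum(time == t & event == 1) / sum(time >= t)
    }
    out[g] <- H
  }
  out
}
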