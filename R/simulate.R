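#' Simulate Hardy-Weinberg genotypes
#'
#' Each SNP is drawn i.i.d. with genotype probabilities
#' \eqn{((1-q)^2, 2q(1-q), q^2)} at minor-allele frequency \eqn{q}, i.e.
#' dosage ~ Binomial(2, q).
#'
#' @param n Number of subjects.
#' @param mafs Named vector of minor-allele frequencies in (0, 0.5].
#' @param seed Integer seed.
#' @return Integer dosage matrix, subjects x SNPs.
#' @export
simulate_genotypes <- function(n, mafs, seed = 1) {
  if (any(mafs <= 0 | mafs > 0.5))
    abort("minor allele frequencies must lie in (0, 0.5]",
          class = "riskforest_config_error")
  set.seed(seed)
  g <- matrix(rbinom(n * length(mafs), 2L, rep(mafs, each = n)),
              nrow = n, ncol = length(mafs))
  colnames(g) <- names(mafs) %||% sprintf("SNP_%03d", seq_along(mafs))
  storage.mode(g) <- "integer"
  g
}

# mean-preserving truncated normal: solve for the latent location so the
# truncated mean equals the requested one, then sample by inverse CDF.
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (is.infinite(lo) && is.infinite(hi)) return(rnorm(n, mean, sd))
  trunc_mean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    z <- pnorm(b) - pnorm(a)
    mu + sd * (dnorm(a) - dnorm(b)) / z
  }
  mu <- uniroot(function(m) trunc_mean(m) - mean,
                interval = mean + c(-4, 4) * sd, extendInt = "yes")$root
  a <- pnorm((lo - mu) / sd); b <- pnorm((hi - mu) / sd)
  qnorm(a + runif(n) * (b - a)) * sd + mu
}

draw_covariate <- function(n, spec) {
  switch(spec$dist,
    normal = rnorm_trunc(n, spec$mean, spec$sd,
                         spec$min %||% -Inf, spec$max %||% Inf),
    gamma = rgamma(n, shape = spec$shape, scale = spec$mean / spec$shape),
    zi_gamma = {
      pos <- runif(n) >= spec$p_zero
      x <- numeric(n)
      x[pos] <- rgamma(sum(pos), shape = spec$shape,
                       scale = spec$mean / spec$shape)
      x
    },
    bernoulli = as.numeric(runif(n) < spec$p),
    mixture_uniform = {
      w <- vapply(spec$components, function(co) co$weight, numeric(1))
      k <- sample.int(length(w), n, replace = TRUE, prob = w)
      lo <- vapply(spec$components, function(co) co$min, numeric(1))
      hi <- vapply(spec$components, function(co) co$max, numeric(1))
      lo[k] + runif(n) * (hi[k] - lo[k])
    },
    constant = rep(spec$value, n),
    abort(paste0("unknown distribution family '", spec$dist, "'"),
          class = "riskforest_config_error")
  )
}

#' Simulate lifestyle covariates
#'
#' @param n Number of subjects.
#' @param covariate_specs Named distribution descriptors
#'   ([default_covariate_specs()]).
#' @param seed Integer seed.
#' @return Tibble with one column per covariate.
#' @export
simulate_lifestyles <- function(n, covariate_specs = default_covariate_specs(),
                                seed = 1) {
  set.seed(seed)
  tibble::as_tibble(lapply(covariate_specs, function(sp)
    draw_covariate(n, sp)))
}

#' Calibrate the baseline hazard to a target event fraction
#'
#' With a constant baseline hazard \eqn{\lambda}, subject-level rate
#' \eqn{\lambda e^{\eta_i}} and administrative censoring
#' \eqn{C \sim U(a, b)}, the event probability has the closed form
#' \eqn{1 - (e^{-ra} - e^{-rb}) / (r (b - a))} with \eqn{r = \lambda
#' e^{\eta_i}}. This solves for \eqn{\lambda} so the mean over subjects
#' matches the target fraction.
#'
#' @param eta Linear predictors (one per subject; use 0 for a null cohort).
#' @param followup Censoring window `c(a, b)` in years.
#' @param target Target marginal event fraction.
#' @return Baseline hazard per year.
#' @export
calibrate_baseline_hazard <- function(eta, followup, target) {
  a <- followup[1]; b <- followup[2]
  p_event <- function(loglam) {
    r <- exp(loglam + eta)
    if (b > a) {
      mean(1 - (exp(-r * a) - exp(-r * b)) / (r * (b - a)))
    } else {
      mean(1 - exp(-r * a))
    }
  }
  exp(uniroot(function(l) p_event(l) - target, c(-20, 2),
              tol = 1e-12)$root)
}

#' Simulate a right-censored proportional-hazards outcome
#'
#' Event times are exponential with rate `baseline_hazard * exp(eta)` where
#' `eta` collects the planted main and interaction effects; censoring is
#' administrative at a uniform time in `followup`.
#'
#' @param design Data frame / tibble of design columns.
#' @param log_hr Named log hazard ratios over design columns.
#' @param interactions List of `list(a =, b =, log_hr =)` product terms.
#' @param baseline_hazard Constant per-year baseline hazard.
#' @param followup Censoring window `c(min, max)` years.
#' @param seed Integer seed.
#' @return Tibble with `time_years` and `event`.
#' @export
simulate_survival <- function(design, log_hr = NULL, interactions = NULL,
                              baseline_hazard, followup = c(12, 20),
                              seed = 1) {
  n <- nrow(design)
  eta <- linear_predictor(design, log_hr, interactions)
  set.seed(seed)
  cens <- runif(n, followup[1], followup[2])
  t_event <- rexp(n, rate = baseline_hazard * exp(eta))
  event <- as.integer(t_event <= cens)
  tibble::tibble(time_years = pmin(t_event, cens), event = event)
}

linear_predictor <- function(design, log_hr, interactions) {
  n <- nrow(design)
  eta <- numeric(n)
  for (nm in names(log_hr)) {
    x <- design[[nm]]
    if (is.null(x))
      abort(paste0("log_hr names a column '", nm, "' absent from the design"),
            class = "riskforest_config_error")
    eta <- eta + log_hr[[nm]] * x
  }
  for (it in interactions %||% list()) {
    a <- design[[it$a]]; b <- design[[it$b]]
    if (is.null(a) || is.null(b))
      abort("interaction term names a column absent from the design",
            class = "riskforest_config_error")
    eta <- eta + it$log_hr * a * b
  }
  if (any(!is.finite(eta)))
    abort("non-finite linear predictor",
          class = "riskforest_simulation_error")
  eta
}

#' Simulate a full cohort
#'
#' Draws genotypes, lifestyle covariates and the survival outcome under a
#' [sim_spec()], with the baseline hazard calibrated to the configured
#' target event fraction when not fixed. A fixed seed reproduces the
#' cohort exactly.
#'
#' @param spec A [sim_spec()].
#' @param seed Integer master seed; sub-seeds for genotypes, covariates and
#'   the outcome are derived deterministically from it.
#' @return A [cohort()]; the realized baseline hazard is attached as
#'   attribute `"baseline_hazard"`.
#' @export
simulate_cohort <- function(spec = sim_spec(), seed = 1) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$n
  g <- simulate_genotypes(n, spec$mafs, derive_seed(seed, "genotypes"))
  covs <- simulate_lifestyles(n, spec$covariate_specs,
                              derive_seed(seed, "lifestyles"))
  design <- dplyr::bind_cols(covs, tibble::as_tibble(g))
  for (nm in names(spec$indicators %||% list())) {
    ind <- spec$indicators[[nm]]
    design[[nm]] <- as.numeric(design[[ind$var]] %in% ind$in_set)
  }
  eta <- linear_predictor(design, spec$log_hr, spec$interactions)
  lambda <- spec$baseline_hazard %||%
    calibrate_baseline_hazard(eta, spec$followup, spec$event_target)
  out <- simulate_survival(design, spec$log_hr, spec$interactions, lambda,
                           spec$followup, derive_seed(seed, "survival"))
  subj <- tibble::tibble(
    subject_id = sprintf("S%06d", seq_len(n)),
    time_years = out$time_years,
    event = out$event
  )
  info <- tibble::tibble(
    snp_id = names(spec$mafs),
    gene = sprintf("GENE_%03d", seq_along(spec$mafs)),
    maf = unname(spec$mafs)
  )
  res <- cohort(subj, g, covs, info)
  attr(res, "baseline_hazard") <- lambda
  res
}
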