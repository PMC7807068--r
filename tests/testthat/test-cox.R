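partial_loglik <- function(b, time, event, x) {
  # no ties assumed: Breslow = Efron = exact
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
  }
  ll
}

grid_max <- function(f, lo = -5, hi = 5, rounds = 60) {
  for (r in seq_len(rounds)) {
    bs <- seq(lo, hi, length.out = 31)
    ll <- vapply(bs, f, numeric(1))
    ctr <- bs[which.max(ll)]
    w <- (hi - lo) / 10
    lo <- ctr - w; hi <- ctr + w
  }
  ctr
}

test_that("Cox coefficients match the partial-likelihood grid oracle", {
  df <- tibble::tibble(
    time_years = c(1.1, 2.4, 3.2, 4.7, 5.3, 6.1, 7.8, 9.5),
    event = c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 0L),
    grp = c(1, 0, 1, 1, 0, 0, 1, 0))
  fit <- cox_fit(df, "grp")
  b_hat <- log(tidy(fit, adjust = FALSE)$hr[1])
  b_oracle <- grid_max(function(b)
    partial_loglik(b, df$time_years, df$event, df$grp))
  expect_equal(b_hat, b_oracle, tolerance = 1e-6)

  # randomized no-tie fixtures up to 10 subjects
  set.seed(91)
  for (r in 1:5) {
    n <- sample(6:10, 1)
    df <- tibble::tibble(time_years = sample(seq(1, 30, by = 0.5), n),
                         event = rbinom(n, 1, 0.7),
                         x = rnorm(n))
    if (sum(df$event) < 3) next
    fit <- try(cox_fit(df, "x"), silent = TRUE)
    if (inherits(fit, "try-error")) next  # monotone likelihood draw
    b_hat <- log(tidy(fit, adjust = FALSE)$hr[1])
    if (abs(b_hat) > 4) next
    b_oracle <- grid_max(function(b)
      partial_loglik(b, df$time_years, df$event, df$x))
    expect_equal(b_hat, b_oracle, tolerance = 1e-6)
  }
})

test_that("null covariates yield hazard ratios near one", {
  inside <- vapply(1:20, function(s) {
    fr <- sim_frame(n = 5000, n_snps = 1, seed = 500 + s,
                    event_target = 0.25)
    fr$z <- rnorm(5000) > 0
    hr <- tidy(cox_fit(fr, "z"), adjust = FALSE)$hr[1]
    hr >= 0.9 && hr <= 1.1
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("BH adjustment reproduces the step-up arithmetic", {
  expect_equal(bh_adjust(0.03), 0.03)  # single p unchanged
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(92)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  # monotone in the ordered sequence
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("trend test uses exact linear coding of the score", {
  fr <- sim_frame(n = 5000, n_snps = 1, seed = 93, event_target = 0.1)
  set.seed(93)
  fr$C <- sample(0:2, 5000, replace = TRUE)
  p1 <- trend_test(fr, "C")
  fit <- survival::coxph(survival::Surv(time_years, event) ~ C, data = fr)
  p2 <- summary(fit)$coefficients["C", "Pr(>|z|)"]
  expect_equal(p1, p2, tolerance = 1e-9)
  expect_error(trend_test(dplyr::mutate(fr, C = 1), "C"),
               class = "riskforest_undefined_error")
})

test_that("a monotone planted dose-response is detected", {
  sp <- sim_spec(n = 5000, n_snps = 1,
                 covariate_specs = list(C = list(
                   dist = "mixture_uniform",
                   components = list(list(weight = .5, min = 0, max = 0),
                                     list(weight = .3, min = 1, max = 1),
                                     list(weight = .2, min = 2, max = 2)))),
                 log_hr = c(C = log(2)), event_target = 0.08)
  fr <- as_analysis_frame(simulate_cohort(sp, seed = 94))
  expect_lt(trend_test(fr, "C"), 0.001)
})

test_that("Schoenfeld residuals behave per the score equations", {
  fr <- sim_frame(n = 1000, n_snps = 2, seed = 95, event_target = 0.15)
  fr$z <- rnorm(1000)
  fit <- cox_fit(fr, c("SNP_001", "z"))
  resid <- residuals(fit$fit, type = "schoenfeld")
  expect_lt(max(abs(colSums(resid))), 1e-6)
  chk <- schoenfeld_check(fit)
  expect_setequal(chk$table$term, c("SNP_001", "z"))
  expect_true(all(chk$table$p.value >= 0 & chk$table$p.value <= 1))
  expect_true(all(c("time", "term", "residual") %in% names(chk$residuals)))
})

test_that("joint-effect tables are complete with a unit reference", {
  sp <- sim_spec(n = 6000, n_snps = 1,
                 covariate_specs = list(g = list(dist = "bernoulli", p = .3),
                                        e = list(dist = "bernoulli", p = .3)),
                 log_hr = c(g = log(2), e = log(2)), event_target = 0.12)
  fr <- as_analysis_frame(simulate_cohort(sp, seed = 96))
  fr$C <- combine_gene_lifestyle(fr$g, fr$e)
  jt <- joint_effect_table(fr, "C", "e")
  expect_equal(jt$hr[jt$stratum == "total" & jt$level == 0], 1)
  for (s in c("total", "low", "high")) {
    expect_equal(sum(jt$n[jt$stratum == s]),
                 if (s == "total") 6000 else sum(fr$e == (s == "high")))
  }
  est <- !is.na(jt$p.value)
  expect_true(all(jt$p.adjusted[est] >= jt$p.value[est] - 1e-15))
  expect_lt(attr(jt, "p_trend"), 0.01)
  expect_error(joint_effect_table(fr, "C", "e", covariates = "e"),
               class = "riskforest_config_error")
})

test_that("multiplicative generation gives a null product term", {
  hrs <- vapply(1:6, function(s) {
    sp <- sim_spec(n = 6000, n_snps = 1,
                   covariate_specs = list(
                     g = list(dist = "bernoulli", p = .3),
                     e = list(dist = "bernoulli", p = .3)),
                   log_hr = c(g = log(2), e = log(2)), event_target = 0.12)
    fr <- as_analysis_frame(simulate_cohort(sp, seed = 600 + s))
    interaction_test(fr, "g", "e")$product_hr
  }, numeric(1))
  expect_gte(mean(hrs), 0.85)
  expect_lte(mean(hrs), 1.18)
})

test_that("additive-risk generation gives RERI near zero", {
  reri <- vapply(1:5, function(s) {
    set.seed(700 + s)
    n <- 4000
    g <- rbinom(n, 1, 0.35); e <- rbinom(n, 1, 0.35)
    rate <- 0.004 * (1 + 1.2 * g + 1.2 * e)  # additive hazards
    t_ev <- rexp(n, rate)
    cens <- runif(n, 12, 20)
    df <- tibble::tibble(time_years = pmin(t_ev, cens),
                         event = as.integer(t_ev <= cens), g = g, e = e)
    unlist(interaction_test(df, "g", "e")[c("reri", "reri_conf.low",
                                            "reri_conf.high")])
  }, numeric(3))
  expect_lt(abs(mean(reri[1, ])), 0.25)
  covers <- mean(reri[2, ] <= 0 & 0 <= reri[3, ])
  expect_gte(covers, 0.6)
})

test_that("constant factors are rejected by the interaction test", {
  fr <- sim_frame(n = 200, n_snps = 1, seed = 97, event_target = 0.3)
  fr$g <- rbinom(200, 1, 0.5)
  fr$e <- 0
  expect_error(interaction_test(fr, "g", "e"),
               class = "riskforest_config_error")
})
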