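fake_forest <- function(trees, vars) {
  structure(list(trees = trees,
                 X = matrix(0, 1, length(vars),
                            dimnames = list(NULL, vars)),
                 col_map = setNames(vars, vars), vars = vars),
            class = "rsf")
}

test_that("log-rank split statistic matches the hand-computed oracle", {
  # identical survival in both groups: statistic is 0 by symmetry
  tt <- c(1, 2, 1, 2); ev <- c(1, 1, 1, 1); gr <- c(1, 1, 0, 0)
  expect_equal(abs(riskforest:::cpp_logrank_statistic(tt, ev, gr)), 0)

  # 4 subjects, all events, groups (A, A, B, B): 2x2 tables by hand
  tt <- c(1, 2, 3, 4); ev <- c(1L, 1L, 1L, 1L); gr <- c(1L, 1L, 0L, 0L)
  expect_equal(riskforest:::cpp_logrank_statistic(tt, ev, gr),
               logrank_oracle(tt, ev, gr), tolerance = 1e-10)

  # censored mixed fixtures
  set.seed(8)
  for (r in 1:20) {
    n <- sample(6:15, 1)
    tt <- sample(1:8, n, replace = TRUE) + 0
    ev <- rbinom(n, 1, 0.7)
    gr <- rbinom(n, 1, 0.5)
    if (sum(ev) == 0 || length(unique(gr)) < 2) next
    got <- riskforest:::cpp_logrank_statistic(tt, ev, as.integer(gr))
    want <- logrank_oracle(tt, ev, gr)
    if (is.finite(want)) expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("split search returns the argmax of a brute-force scan", {
  set.seed(21)
  for (r in 1:10) {
    n <- 10
    x <- round(runif(n, 0, 5), 1)
    tt <- sample(1:6, n, replace = TRUE) + 0
    ev <- rep(1L, n)
    # brute force over all admissible cut points with the oracle statistic
    cuts <- sort(unique(x)); cuts <- cuts[-length(cuts)]
    stats <- vapply(cuts, function(cu) {
      gl <- as.integer(x <= cu)
      if (sum(gl) == 0 || sum(gl) == n) return(NA_real_)
      if (sum(ev[gl == 1]) < 1 || sum(ev[gl == 0]) < 1) return(NA_real_)
      abs(logrank_oracle(tt, ev, gl))
    }, numeric(1))
    if (all(is.na(stats))) next
    best <- riskforest:::cpp_best_split(x, tt, ev, nsplit = 0L,
                                        min_node_events = 1L)
    expect_equal(best$statistic, max(stats, na.rm = TRUE),
                 tolerance = 1e-10)
    expect_equal(abs(stats[match(best$cut, cuts)]), best$statistic,
                 tolerance = 1e-10)
  }
})

test_that("bootstrap resampling uses ~63% of subjects, leaving ~37% OOB", {
  fr <- sim_frame(n = 10000, n_snps = 2, seed = 31)
  fit <- grow_forest(fr, c("SNP_001", "SNP_002"),
                     forest_config(n_trees = 200, max_depth = 1, seed = 31))
  distinct <- mean(colMeans(fit$inbag > 0))
  expect_equal(distinct, 0.63, tolerance = 0.005 / 0.63)
  expect_equal(1 - distinct, 0.37, tolerance = 0.005 / 0.37)
})

test_that("a strongly predictive variable dominates the root split", {
  sp <- sim_spec(n = 2000, mafs = setNames(rep(0.3, 20),
                                           sprintf("SNP_%03d", 1:20)),
                 covariate_specs = list(expose = list(dist = "bernoulli",
                                                      p = 0.5)),
                 log_hr = c(expose = log(4)), event_target = 0.15)
  fr <- as_analysis_frame(simulate_cohort(sp, seed = 32))
  vars <- c(sprintf("SNP_%03d", 1:20), "expose")
  fit <- grow_forest(fr, vars,
                     forest_config(n_trees = 100, mtry = 21, seed = 32))
  root_vars <- vapply(fit$trees, function(tr) tr$var[1], integer(1))
  expect_gt(mean(root_vars == match("expose", colnames(fit$X))), 0.5)
})

test_that("a single unsplit tree reproduces the Nelson-Aalen estimator", {
  df <- tibble::tibble(time_years = c(1, 2, 3, 4, 5),
                       event = c(1L, 1L, 0L, 1L, 0L),
                       x = c(0.1, 0.5, 0.2, 0.9, 0.3))
  fit <- grow_forest(df, "x",
                     forest_config(n_trees = 1, bootstrap = FALSE,
                                   min_node_events = 99, seed = 1))
  chf <- predict(fit, type = "chf")
  grid <- attr(chf, "time")
  expect_equal(grid, c(1, 2, 4))
  oracle <- nelson_aalen_oracle(df$time_years, df$event, grid)
  expect_equal(oracle, c(1 / 5, 1 / 5 + 1 / 4, 1 / 5 + 1 / 4 + 1 / 2))
  for (i in 1:5) expect_equal(unname(chf[i, ]), oracle, tolerance = 1e-12)

  inc <- predict(fit, type = "incidence")
  expect_true(all(inc >= 0 & inc <= 1))
  expect_true(all(apply(inc, 1, function(z) all(diff(z) >= 0))))
})

test_that("degenerate cohorts are rejected", {
  df <- tibble::tibble(time_years = 1:5 + 0, event = rep(0L, 5),
                       x = rnorm(5))
  expect_error(grow_forest(df, "x", forest_config(n_trees = 2)),
               class = "riskforest_fit_error")
})

test_that("concordance matches brute-force pair enumeration", {
  # perfect and reversed orderings
  tt <- 1:6 + 0; ev <- rep(1L, 6)
  expect_equal(harrell_cindex(tt, ev, 6:1), 1)
  expect_equal(harrell_cindex(tt, ev, 1:6), 0)
  # 8-subject censored fixture
  tt <- c(2, 5, 3, 3, 8, 1, 7, 4)
  ev <- c(1L, 0L, 1L, 0L, 0L, 1L, 1L, 1L)
  rk <- c(5, 1, 4, 2, 0.5, 6, 1, 3)
  expect_equal(harrell_cindex(tt, ev, rk), cindex_oracle(tt, ev, rk),
               tolerance = 1e-12)
  # randomized fixtures with ties and NAs
  set.seed(33)
  for (r in 1:25) {
    n <- sample(5:25, 1)
    tt <- sample(1:10, n, replace = TRUE) + 0
    ev <- rbinom(n, 1, 0.6)
    rk <- sample(1:5, n, replace = TRUE) + 0
    if (r %% 4 == 0) rk[sample(n, 1)] <- NA
    want <- cindex_oracle(tt, ev, rk)
    got <- harrell_cindex(tt, ev, rk)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("minimal depth follows the first-split / unused-variable rules", {
  # root split on X: MD(X) = 0; Y unused in a depth-1 tree contributes 2
  t1 <- list(var = c(1L, 0L, 0L), depth = c(0L, 1L, 1L))
  md <- minimal_depth(fake_forest(list(t1), c("X", "Y")))
  expect_equal(md$minimal_depth, c(0, 2))

  # depth-3 tree (deepest node at depth 3): unused variable contributes 4
  t2 <- list(var = c(1L, 1L, 0L, 1L, 0L, 0L, 0L),
             depth = c(0L, 1L, 1L, 2L, 2L, 3L, 3L))
  md <- minimal_depth(fake_forest(list(t2), c("X", "Y")))
  expect_equal(md$minimal_depth[md$variable == "Y"], 4)

  # two trees average: X first split at 0 and 1 -> 0.5; Y at 1 and 4 (unused)
  t3 <- list(var = c(2L, 1L, 0L, 0L, 0L), depth = c(0L, 1L, 1L, 2L, 2L))
  md <- minimal_depth(fake_forest(list(t2, t3), c("X", "Y")))
  expect_equal(md$minimal_depth[md$variable == "X"], mean(c(0, 1)))
  expect_equal(md$minimal_depth[md$variable == "Y"], mean(c(4, 0)))
})

test_that("permutation importance is zero for constants, calibrated for noise", {
  fr <- sim_frame(n = 300, n_snps = 3, seed = 41, event_target = 0.2)
  fr$const <- 1
  fit <- grow_forest(fr, c(sprintf("SNP_%03d", 1:3), "const"),
                     forest_config(n_trees = 30, seed = 41, vimp_reps = 2))
  vi <- permutation_vimp(fit)
  expect_identical(vi$vimp[vi$variable == "const"], 0)

  # pure-noise variable: mean VIMP within 2 SE of zero across 50 cohorts
  vimps <- vapply(1:50, function(s) {
    fr <- sim_frame(n = 150, n_snps = 4, seed = 100 + s, event_target = 0.25)
    fit <- grow_forest(fr, sprintf("SNP_%03d", 1:4),
                       forest_config(n_trees = 30, seed = s, vimp_reps = 2))
    permutation_vimp(fit)$vimp[1]
  }, numeric(1))
  expect_lt(abs(mean(vimps)), 2 * sd(vimps) / sqrt(50))

  # planted strong variable: VIMP > 0 in at least 95% of 50 cohorts
  pos <- vapply(1:50, function(s) {
    fr <- sim_frame(n = 250, n_snps = 3, seed = 200 + s,
                    log_hr = c(SNP_001 = log(3)), event_target = 0.25)
    fit <- grow_forest(fr, sprintf("SNP_%03d", 1:3),
                       forest_config(n_trees = 50, seed = s, vimp_reps = 2))
    permutation_vimp(fit)$vimp[1] > 0
  }, logical(1))
  expect_gte(mean(pos), 0.95)
})

test_that("forests are deterministic under a fixed seed", {
  fr <- sim_frame(n = 400, n_snps = 4, seed = 51, event_target = 0.15)
  cfg <- forest_config(n_trees = 25, seed = 9)
  f1 <- grow_forest(fr, sprintf("SNP_%03d", 1:4), cfg)
  f2 <- grow_forest(fr, sprintf("SNP_%03d", 1:4), cfg)
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$inbag, f2$inbag)
  expect_equal(oob_cindex(f1), oob_cindex(f2))
})
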