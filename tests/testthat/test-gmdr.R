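test_that("score residuals follow the null-model score equations", {
  # intercept-only model with balanced events: scores are exactly +/- 0.5
  df <- tibble::tibble(time_years = 1:10 + 0,
                       event = rep(c(0L, 1L), 5))
  sc <- gmdr_scores(df)
  expect_equal(sort(unique(sc)), c(-0.5, 0.5))
  expect_equal(sum(sc), 0, tolerance = 1e-8)

  # with a covariate, scores still sum to zero (intercept in the null model)
  df$age <- rnorm(10, 66, 5)
  expect_equal(sum(gmdr_scores(df, covariates = "age")), 0,
               tolerance = 1e-8)
})

test_that("logistic residuals match a brute-force likelihood maximization", {
  df <- tibble::tibble(time_years = rep(1, 6),
                       event = c(0L, 0L, 1L, 0L, 1L, 1L),
                       x = c(-1.2, -0.5, 0.1, 0.4, 0.9, 1.7))
  sc <- gmdr_scores(df, covariates = "x")
  # nested grid search over (b0, b1)
  loglik <- function(b0, b1) {
    p <- 1 / (1 + exp(-(b0 + b1 * df$x)))
    sum(df$event * log(p) + (1 - df$event) * log(1 - p))
  }
  ctr <- c(0, 0); width <- 8
  for (round in 1:40) {
    b0s <- seq(ctr[1] - width, ctr[1] + width, length.out = 21)
    b1s <- seq(ctr[2] - width, ctr[2] + width, length.out = 21)
    ll <- outer(b0s, b1s, Vectorize(loglik))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    ctr <- c(b0s[ix[1]], b1s[ix[2]])
    width <- width / 2.5
  }
  p_hat <- 1 / (1 + exp(-(ctr[1] + ctr[2] * df$x)))
  expect_equal(sc, df$event - p_hat, tolerance = 1e-6)
})

test_that("cell classification follows the sign rule with conservative ties", {
  geno <- tibble::tibble(s1 = c(0L, 0L, 0L, 1L, 1L, 2L),
                         s2 = c(0L, 0L, 0L, 1L, 1L, 0L))
  sc <- c(0.5, 0.5, -0.5, 0.3, -0.3, -0.1)
  cells <- gmdr_classify(sc, geno, c("s1", "s2"))
  expect_equal(cells$label[cells$cell == "0/0"], "high")  # sum +0.5
  expect_equal(cells$label[cells$cell == "1/1"], "low")   # sum exactly 0
  expect_equal(cells$label[cells$cell == "2/0"], "low")
  # exhaustive hand classification of every observed cell
  hand <- tapply(sc, paste(geno$s1, geno$s2, sep = "/"), sum)
  for (cl in names(hand)) {
    expect_equal(cells$label[cells$cell == cl],
                 if (hand[[cl]] > 0) "high" else "low")
  }
  expect_error(gmdr_classify(sc, geno, rep("s1", 6)),
               class = "riskforest_config_error")
})

test_that("cross-validated balanced accuracy has the stated fixed points", {
  # a SNP that perfectly determines the score sign: TBA = 1
  n <- 200
  g <- tibble::tibble(s1 = rep(c(0L, 2L), each = n / 2))
  sc <- ifelse(g$s1 == 2, 1, -1) * runif(n, 0.2, 1)
  cv <- gmdr_cv(sc, g, "s1", folds = 10, seed = 1)
  expect_equal(cv$tba, 1)
  expect_equal(cv$train_ba, 1)

  # single-cell combo predicts everything high: BA = (1 + 0)/2 = 0.5
  g2 <- tibble::tibble(s1 = rep(0L, n))
  sc2 <- c(rep(1, 150), rep(-1, 50))  # positive total in every fold
  cv2 <- gmdr_cv(sc2, g2, "s1", folds = 10, seed = 2)
  expect_equal(cv2$tba, 0.5)
})

test_that("small-instance TBA equals direct enumeration", {
  set.seed(81)
  for (r in 1:5) {
    n <- 30
    g <- tibble::tibble(s1 = sample(0:2, n, replace = TRUE),
                        s2 = sample(0:2, n, replace = TRUE))
    sc <- rnorm(n)
    fold_id <- rep_len(1:5, n)
    # folds occasionally lack a score class; both routes skip them
    got <- suppressWarnings(gmdr_cv(sc, g, c("s1", "s2"),
                                    fold_id = fold_id))
    # enumeration oracle over the 9 cells and 5 folds
    bas <- c()
    for (f in 1:5) {
      train <- fold_id != f
      labs <- list()
      for (a in 0:2) for (b in 0:2) {
        key <- paste(a, b)
        ss <- sum(sc[train & g$s1 == a & g$s2 == b])
        labs[[key]] <- ss > 0
      }
      test <- which(!train)
      pred <- vapply(test, function(i)
        labs[[paste(g$s1[i], g$s2[i])]], logical(1))
      truth <- sc[test] > 0
      if (!any(truth) || all(truth)) next
      sens <- sum(pred & truth) / sum(truth)
      spec <- sum(!pred & !truth) / sum(!truth)
      bas <- c(bas, (sens + spec) / 2)
    }
    expect_equal(got$tba, mean(bas), tolerance = 1e-12)
  }
})

test_that("TBA is calibrated at 0.5 under score permutation", {
  fr <- sim_frame(n = 2000, n_snps = 3, seed = 82)
  sc <- gmdr_scores(fr)
  set.seed(82)
  tbas <- vapply(1:100, function(b)
    gmdr_cv(sample(sc), fr[sprintf("SNP_%03d", 1:3)],
            c("SNP_001", "SNP_002"), folds = 10, seed = b)$tba,
    numeric(1))
  expect_equal(mean(tbas), 0.5, tolerance = 0.01 / 0.5)
})

test_that("model search enumerates orders and finds planted interactions", {
  fr <- sim_frame(n = 3000, n_snps = 10, seed = 83,
                  indicators = list(
                    i1 = list(var = "SNP_001", in_set = 1:2),
                    i2 = list(var = "SNP_002", in_set = 1:2)),
                  interactions = list(list(a = "i1", b = "i2",
                                           log_hr = log(3))),
                  event_target = 0.15)
  sc <- gmdr_scores(fr)
  gm <- gmdr_search(sc, fr[sprintf("SNP_%03d", 1:10)],
                    sprintf("SNP_%03d", 1:10), max_order = 2, folds = 10,
                    seed = 83, strata = fr$event)
  expect_equal(gm$order, 1:2)
  expect_true(all(unlist(gm$combo) %in% sprintf("SNP_%03d", 1:10)))
  expect_setequal(gm$combo[gm$order == 2][[1]], c("SNP_001", "SNP_002"))
  expect_equal(gm$cvc[2], 10)  # dominant signal wins every fold
  expect_true(all(gm$tba >= 0 & gm$tba <= 1))
  expect_error(
    gmdr_search(sc, fr[sprintf("SNP_%03d", 1:10)],
                sprintf("SNP_%03d", 1:10), max_order = 2, max_pool = 5),
    class = "riskforest_config_error")
})

test_that("permutation p-values respect the add-one floor and invariances", {
  fr <- sim_frame(n = 400, n_snps = 2, seed = 84, event_target = 0.3)
  sc <- gmdr_scores(fr)
  g <- fr[sprintf("SNP_%03d", 1:2)]
  pt <- gmdr_permutation_test(sc, g, "SNP_001", n_perm = 49, seed = 84)
  expect_gte(pt$p, 1 / 50)
  expect_lte(pt$p, 1)
  # invariant to positive rescaling of the scores
  pt2 <- gmdr_permutation_test(sc * 7.3, g, "SNP_001", n_perm = 49,
                               seed = 84)
  expect_equal(pt$p, pt2$p)

  # a strong signal hits the floor
  g2 <- tibble::tibble(s = rep(c(0L, 2L), each = 100))
  sc2 <- ifelse(g2$s == 2, 1, -1) * runif(200, 0.2, 1)
  pt3 <- gmdr_permutation_test(sc2, g2, "s", n_perm = 99, seed = 1)
  expect_equal(pt3$p, 1 / 100)
})

test_that("best-model selection follows the TBA/CVC/significance rule", {
  res <- tibble::tibble(
    order = 1:2, model = c("m1", "m2"), combo = list("a", c("a", "b")),
    train_ba = c(0.55, 0.54), tba = c(0.5382, 0.5270),
    cvc = c(10L, 8L), p_value = c(0.0010, 0.0010))
  best <- gmdr_select_best(res, folds = 10)
  expect_equal(best$model, "m1")
  expect_true(best$significant)

  # no significant model: full CVC takes precedence, then highest TBA
  res2 <- tibble::tibble(
    order = 1:4, model = paste0("m", 1:4), combo = as.list(letters[1:4]),
    train_ba = rep(0.5, 4), tba = c(0.5306, 0.5233, 0.5564, 0.5486),
    cvc = c(10L, 5L, 10L, 10L), p_value = c(0.1719, 0.3770, 0.0547, 0.0547))
  best2 <- gmdr_select_best(res2, folds = 10)
  expect_equal(best2$tba, 0.5564)
  expect_false(best2$significant)
  expect_equal(best2$selection_rule, "cvc_fallback")

  # single candidate selects itself
  best3 <- gmdr_select_best(res[1, ], folds = 10)
  expect_equal(best3$model, "m1")
})
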