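#' Covariate-adjusted GMDR score residuals
#'
#' Generalized multifactor dimensionality reduction classifies multilocus
#' genotype cells by the sign of summed score residuals from a null
#' phenotype model. The default scores the binary event indicator with a
#' logistic null model (`score = y - fitted`), so scores sum to zero
#' whenever the null model contains an intercept; martingale residuals from
#' a null Cox model are available to use the time-to-event information.
#'
#' @param data Modelling frame.
#' @param covariates Adjustment covariates for the null model (`NULL` =
#'   intercept only).
#' @param type `"logistic"` response residuals or `"martingale"` residuals
#'   from a null proportional-hazards model.
#' @param time,event Column names.
#' @return Numeric score vector, one per subject.
#' @export
gmdr_scores <- function(data, covariates = NULL,
                        type = c("logistic", "martingale"),
                        time = "time_years", event = "event") {
  type <- match.arg(type)
  y <- data[[event]]
  assert_binary(y, "event")
  if (type == "logistic") {
    df <- data.frame(.y = y)
    rhs <- "1"
    if (length(covariates)) {
      df <- cbind(df, data[covariates])
      rhs <- paste(covariates, collapse = " + ")
    }
    fit <- glm(as.formula(paste(".y ~", rhs)), data = df,
               family = binomial())
    if (!fit$converged)
      abort("null logistic model did not converge",
            class = "riskforest_fit_error")
    unname(y - fitted(fit))
  } else {
    rhs <- if (length(covariates))
      paste(covariates, collapse = " + ") else "1"
    fit <- survival::coxph(
      as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ", rhs)),
      data = data)
    unname(residuals(fit, type = "martingale"))
  }
}

cell_ids <- function(genotypes, combo) {
  g <- as.matrix(genotypes[, combo, drop = FALSE])
  if (anyNA(g))
    abort("missing genotypes; impute before GMDR",
          class = "riskforest_validation_error")
  as.integer(g %*% 3^(seq_along(combo) - 1)) + 1L
}

cell_labels <- function(scores, cells, train, ncells, threshold) {
  sums <- numeric(ncells)
  tab <- rowsum(scores[train], cells[train])
  sums[as.integer(rownames(tab))] <- tab
  sums > threshold  # tie (sum == threshold) classifies low-risk
}

balanced_accuracy <- function(pred_high, truth_pos) {
  npos <- sum(truth_pos); nneg <- sum(!truth_pos)
  if (npos == 0 || nneg == 0) return(NA_real_)
  ((sum(pred_high & truth_pos) / npos) +
     (sum(!pred_high & !truth_pos) / nneg)) / 2
}

#' Classify multilocus genotype cells as high or low risk
#'
#' Sums the score residuals within each multilocus genotype cell of the
#' factor combination; cells with a positive sum (above `threshold`) are
#' high-risk, cells at or below are low-risk (ties conservatively low).
#' Genotype combinations absent from the data are unclassifiable and do not
#' appear.
#'
#' @param scores Score residuals ([gmdr_scores()]).
#' @param genotypes Data frame or matrix of dosage columns.
#' @param combo Character vector of 1-5 SNP columns.
#' @param threshold Classification threshold (0 by convention).
#' @return Tibble with `cell` (dosage string), `n`, `score_sum`, `label`.
#' @export
gmdr_classify <- function(scores, genotypes, combo, threshold = 0) {
  if (length(combo) > 5)
    abort("factor combinations are limited to 5 SNPs",
          class = "riskforest_config_error")
  cells <- cell_ids(genotypes, combo)
  tab <- rowsum(scores, cells)
  ids <- as.integer(rownames(tab))
  digits <- vapply(ids - 1L, function(v)
    paste(v %/% 3^(seq_along(combo) - 1) %% 3, collapse = "/"),
    character(1))
  tibble::tibble(
    cell = digits, n = as.integer(table(cells)[rownames(tab)]),
    score_sum = as.numeric(tab),
    label = ifelse(tab > threshold, "high", "low")
  )
}

#' Stratified cross-validation folds
#' @noRd
make_folds <- function(n, folds, seed, strata = NULL) {
  set.seed(seed)
  strata <- strata %||% rep(1L, n)
  fold_id <- integer(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_id
}

#' Cross-validated balanced accuracy of a factor combination
#'
#' Ten-fold cross-validation of the high/low cell classification: cells are
#' labelled on the training folds, held-out subjects are predicted by their
#' cell's label (cells empty in training predict low-risk), and truth is a
#' positive score residual. Balanced accuracy is (sensitivity +
#' specificity) / 2; the testing balanced accuracy (TBA) is its mean over
#' folds. Folds whose test part lacks positives or negatives are skipped
#' with a warning. Fold assignment is stratified (by event status when
#' `strata` is supplied) and fixed by `seed`.
#'
#' @param scores Score residuals.
#' @param genotypes Dosage columns.
#' @param combo SNP combination to evaluate.
#' @param folds Number of folds.
#' @param seed Fold-assignment seed.
#' @param strata Optional stratification vector (e.g. the event indicator).
#' @param fold_id Optional explicit fold assignment (overrides `folds`,
#'   `seed`, `strata`).
#' @param threshold Cell classification threshold.
#' @return List with `train_ba`, `tba` and a per-fold tibble.
#' @export
gmdr_cv <- function(scores, genotypes, combo, folds = 10, seed = 1,
                    strata = NULL, fold_id = NULL, threshold = 0) {
  n <- length(scores)
  if (is.null(fold_id)) {
    if (folds < 2 || n < folds)
      abort("need at least 2 folds and n >= folds",
            class = "riskforest_config_error")
    fold_id <- make_folds(n, folds, seed, strata)
  }
  cells <- cell_ids(genotypes, combo)
  ncells <- 3L^length(combo)
  truth <- scores > 0
  res <- purrr::map_dfr(sort(unique(fold_id)), function(f) {
    train <- fold_id != f
    lab <- cell_labels(scores, cells, train, ncells, threshold)
    tibble::tibble(
      fold = f,
      train_ba = balanced_accuracy(lab[cells[train]], truth[train]),
      test_ba = balanced_accuracy(lab[cells[!train]], truth[!train])
    )
  })
  if (anyNA(res$test_ba))
    warn("fold(s) without both positive and negative scores were skipped")
  list(train_ba = mean(res$train_ba, na.rm = TRUE),
       tba = mean(res$test_ba, na.rm = TRUE), folds = res)
}

#' Exhaustive GMDR model search
#'
#' Enumerates every SNP combination at each order, records the top
#' training-balanced-accuracy combination within each cross-validation fold
#' (the basis of cross-validation consistency, CVC), reports the plurality
#' winner per order with its testing balanced accuracy, and optionally
#' attaches a permutation p-value per order.
#'
#' @param scores Score residuals.
#' @param genotypes Dosage columns.
#' @param pool Candidate SNP names (capped at `max_pool`; exhaustive search
#'   beyond that is a combinatorial blow-up and raises an error).
#' @param max_order Largest combination size searched (1-5).
#' @param folds,seed,strata Cross-validation controls (see [gmdr_cv()]).
#' @param n_perm Permutation replicates for per-order p-values (0 = skip).
#' @param max_pool Guard on the pool size.
#' @return A `gmdr_result`: tibble with one row per order (`order`,
#'   `model`, `combo` list-column, `train_ba`, `tba`, `cvc`, `p_value`).
#' @export
gmdr_search <- function(scores, genotypes, pool, max_order = 5, folds = 10,
                        seed = 1, strata = NULL, n_perm = 0,
                        max_pool = 25) {
  if (length(pool) > max_pool)
    abort(sprintf("pool of %d SNPs exceeds the exhaustive-search cap (%d)",
                  length(pool), max_pool),
          class = "riskforest_config_error")
  if (length(pool) < max_order)
    abort("pool smaller than max_order", class = "riskforest_config_error")
  n <- length(scores)
  fold_id <- make_folds(n, folds, seed, strata)
  truth <- scores > 0
  rows <- purrr::map_dfr(seq_len(max_order), function(ord) {
    combos <- combn(pool, ord, simplify = FALSE)
    train_ba <- matrix(NA_real_, length(combos), folds)
    test_ba <- matrix(NA_real_, length(combos), folds)
    for (ci in seq_along(combos)) {
      cells <- cell_ids(genotypes, combos[[ci]])
      ncells <- 3L^ord
      for (f in seq_len(folds)) {
        train <- fold_id != f
        lab <- cell_labels(scores, cells, train, ncells, 0)
        train_ba[ci, f] <- balanced_accuracy(lab[cells[train]], truth[train])
        test_ba[ci, f] <- balanced_accuracy(lab[cells[!train]], truth[!train])
      }
    }
    winners <- apply(train_ba, 2, which.max)
    counts <- table(winners)
    top <- as.integer(names(counts)[counts == max(counts)])
    if (length(top) > 1)  # tie-break: higher mean training accuracy
      top <- top[which.max(rowMeans(train_ba[top, , drop = FALSE]))]
    tibble::tibble(
      order = ord,
      model = paste(combos[[top]], collapse = " + "),
      combo = list(combos[[top]]),
      train_ba = mean(train_ba[top, ], na.rm = TRUE),
      tba = mean(test_ba[top, ], na.rm = TRUE),
      cvc = sum(winners == top)
    )
  })
  if (n_perm > 0) {
    rows$p_value <- vapply(seq_len(nrow(rows)), function(i) {
      gmdr_permutation_test(scores, genotypes, rows$combo[[i]],
                            fold_id = fold_id, n_perm = n_perm,
                            seed = derive_seed(seed, paste0("perm_", i)))$p
    }, numeric(1))
  } else {
    rows$p_value <- NA_real_
  }
  structure(rows, folds = folds,
            class = c("gmdr_result", class(rows)))
}

#' GMDR permutation test
#'
#' Permutes the score residuals against the genotypes `n_perm` times,
#' re-evaluates the testing balanced accuracy of the combination, and
#' reports the one-sided exceedance p-value with the add-one estimator
#' `p = (1 + #{perm TBA >= observed}) / (n_perm + 1)`, whose floor is
#' `1/(n_perm + 1)`.
#'
#' @param scores,genotypes,combo As in [gmdr_cv()].
#' @param folds,seed,strata,fold_id Cross-validation controls.
#' @param n_perm Number of permutations.
#' @return List with `p`, `tba_observed` and the permutation TBAs.
#' @export
gmdr_permutation_test <- function(scores, genotypes, combo, folds = 10,
                                  n_perm = 1000, seed = 1, strata = NULL,
                                  fold_id = NULL) {
  n <- length(scores)
  fold_id <- fold_id %||% make_folds(n, folds, derive_seed(seed, "folds"),
                                     strata)
  cells <- cell_ids(genotypes, combo)
  ncells <- 3L^length(combo)
  eval_tba <- function(sc) {
    truth <- sc > 0
    bas <- vapply(sort(unique(fold_id)), function(f) {
      train <- fold_id != f
      lab <- cell_labels(sc, cells, train, ncells, 0)
      balanced_accuracy(lab[cells[!train]], truth[!train])
    }, numeric(1))
    mean(bas, na.rm = TRUE)
  }
  obs <- eval_tba(scores)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) eval_tba(sample(scores)),
                 numeric(1))
  list(p = (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1),
       tba_observed = obs, tba_perm = perm)
}

#' Select the best GMDR model across orders
#'
#' The best model has the highest TBA among models with full
#' cross-validation consistency (CVC = folds) and permutation p < `alpha`.
#' If no model qualifies, full CVC takes precedence: the highest-TBA model
#' among those with full CVC is chosen and flagged non-significant (falling
#' back to the overall highest TBA if none has full CVC).
#'
#' @param result A `gmdr_result` (or compatible tibble with `tba`, `cvc`,
#'   `p_value`).
#' @param alpha Significance level for the permutation p-value.
#' @param folds Number of folds CVC is out of.
#' @return One-row tibble: the winning model plus `significant` and
#'   `selection_rule` (`"primary"` or `"cvc_fallback"`).
#' @export
gmdr_select_best <- function(result, alpha = 0.05,
                             folds = attr(result, "folds") %||% 10) {
  stopifnot(nrow(result) >= 1)
  tbl <- tibble::as_tibble(result)
  qualified <- !is.na(tbl$p_value) & tbl$p_value < alpha & tbl$cvc == folds
  if (any(qualified)) {
    pick <- which(qualified)[which.max(tbl$tba[qualified])]
    rule <- "primary"; signif <- TRUE
  } else {
    full <- tbl$cvc == folds
    if (any(full)) {
      pick <- which(full)[which.max(tbl$tba[full])]
    } else {
      pick <- which.max(tbl$tba)
    }
    rule <- "cvc_fallback"
    signif <- FALSE
  }
  dplyr::mutate(tbl[pick, ], significant = signif, selection_rule = rule)
}

#' @exportS3Method generics::tidy
tidy.gmdr_result <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"combo")
}

#' @exportS3Method generics::glance
glance.gmdr_result <- function(x, ...) {
  best <- gmdr_select_best(x)
  tibble::tibble(best_model = best$model, best_tba = best$tba,
                 best_cvc = best$cvc, best_p = best$p_value,
                 significant = best$significant)
}
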