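#' Random survival forest configuration
#'
#' @param n_trees Number of bootstrap trees. The profiling analyses this
#'   package reproduces use 5000; simulation tests use far fewer.
#' @param mtry Candidate variables per split; default `ceiling(sqrt(p))`.
#' @param nsplit Random candidate split points per variable (0 = exhaustive
#'   scan over all observed values, used by the oracle tests).
#' @param min_node_events Minimum number of events in each terminal node.
#' @param max_depth Maximum tree depth (0 = unlimited).
#' @param bootstrap Draw bootstrap samples (TRUE); FALSE grows every tree on
#'   the full sample, which makes a single unsplit tree collapse to the
#'   Nelson-Aalen estimator.
#' @param vimp_reps Permutation replicates per variable for importance.
#' @param seed Integer seed fixing the whole forest.
#' @return A `forest_config` object.
#' @export
forest_config <- function(n_trees = 5000, mtry = NULL, nsplit = 10,
                          min_node_events = 3, max_depth = 0,
                          bootstrap = TRUE, vimp_reps = 5, seed = 1) {
  if (n_trees < 1)
    abort("n_trees must be >= 1", class = "riskforest_config_error")
  structure(
    list(n_trees = as.integer(n_trees), mtry = mtry,
         nsplit = as.integer(nsplit),
         min_node_events = as.integer(min_node_events),
         max_depth = as.integer(max_depth), bootstrap = isTRUE(bootstrap),
         vimp_reps = as.integer(vimp_reps), seed = as.integer(seed)),
    class = "forest_config"
  )
}

#' Grow a random survival forest
#'
#' Grows `n_trees` survival trees on bootstrap samples (each using about 63%
#' of the distinct subjects, leaving ~37% out of bag). Nodes are split by
#' the candidate (variable, value) pair maximizing the absolute standardized
#' two-sample log-rank statistic over `mtry` randomly chosen variables and
#' up to `nsplit` random split points each; terminal nodes store
#' Nelson-Aalen cumulative-hazard estimators evaluated on the pooled
#' event-time grid. Genotype dosages are treated as ordered numeric;
#' character/factor covariates are one-hot expanded.
#'
#' @param data Data frame with the follow-up time, event indicator and
#'   predictor columns (e.g. from [as_analysis_frame()]).
#' @param vars Character vector of predictor columns; default every column
#'   except time, event and `subject_id`.
#' @param config A [forest_config()].
#' @param time,event Column names of follow-up time and event indicator.
#' @return An object of class `rsf`.
#' @export
grow_forest <- function(data, vars = NULL, config = forest_config(),
                        time = "time_years", event = "event") {
  vars <- vars %||% setdiff(names(data), c(time, event, "subject_id"))
  if (length(vars) == 0)
    abort("no predictor variables", class = "riskforest_config_error")
  tt <- as.numeric(data[[time]])
  ev <- as.integer(data[[event]])
  if (sum(ev) < 2)
    abort("cohort has fewer than 2 events; cannot grow a survival forest",
          class = "riskforest_fit_error")
  des <- build_design(data, vars)
  mtry <- config$mtry %||% ceiling(sqrt(ncol(des$X)))
  set.seed(config$seed)
  fit <- cpp_grow_forest(des$X, tt, ev, config$n_trees,
                         as.integer(mtry), config$nsplit,
                         config$min_node_events, config$max_depth,
                         config$bootstrap)
  structure(
    list(trees = fit$trees, chf = fit$chf, grid = as.numeric(fit$grid),
         inbag = fit$inbag, X = des$X, Xt = t(des$X), col_map = des$map,
         levels = des$levels, vars = vars, time = tt, event = ev,
         config = config, mtry = as.integer(mtry)),
    class = "rsf"
  )
}

#' @export
print.rsf <- function(x, ...) {
  cat("<rsf> ", length(x$trees), " trees, ", ncol(x$X),
      " design columns (", length(x$vars), " variables), n = ",
      nrow(x$X), ", events = ", sum(x$event), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.rsf <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$X), n_events = sum(x$event), n_trees = length(x$trees),
    mtry = x$mtry, oob_cindex = oob_cindex(x)
  )
}

design_for <- function(object, newdata) {
  if (is.null(newdata)) return(object$X)
  des <- build_design(newdata, object$vars, levels_map = object$levels)
  if (!identical(colnames(des$X), colnames(object$X)))
    abort("newdata design does not match the training design",
          class = "riskforest_prediction_error")
  des$X
}

#' Predict from a random survival forest
#'
#' @param object An `rsf` forest.
#' @param newdata Data frame of predictors (default: training data).
#' @param type `"chf"` for the ensemble cumulative hazard (matrix subjects x
#'   grid, with the event-time grid in `attr(, "time")`), `"incidence"` for
#'   the predicted cumulative incidence `1 - exp(-CHF)`, or `"mortality"`
#'   for the ensemble mortality (sum of the CHF over the grid), the risk
#'   score used for concordance.
#' @param oob Use only trees where each subject is out of bag (training data
#'   only).
#' @param ... Unused.
#' @return Matrix (chf/incidence) or numeric vector (mortality).
#' @export
predict.rsf <- function(object, newdata = NULL,
                        type = c("chf", "incidence", "mortality"),
                        oob = FALSE, ...) {
  type <- match.arg(type)
  if (oob && !is.null(newdata))
    abort("oob predictions are defined for the training data only",
          class = "riskforest_prediction_error")
  Xt <- if (is.null(newdata)) object$Xt else t(design_for(object, newdata))
  chf <- cpp_ensemble_chf(object$trees, object$chf, Xt, object$inbag, oob)
  if (type == "mortality") return(rowSums(chf))
  if (type == "incidence") chf <- 1 - exp(-chf)
  attr(chf, "time") <- object$grid
  chf
}

#' Tidy ensemble cumulative-incidence curves
#'
#' Long-format predicted cumulative breast-cancer incidence for a set of
#' subjects, convenient for plotting dose-response profiles.
#'
#' @param object An `rsf` forest.
#' @param newdata Data frame of predictors (default training data).
#' @param group Optional vector labelling rows of `newdata`; curves are
#'   averaged within groups.
#' @return Tibble with `group`, `time` and `incidence`.
#' @export
ensemble_incidence <- function(object, newdata = NULL, group = NULL) {
  inc <- predict(object, newdata, type = "incidence")
  grid <- attr(inc, "time")
  group <- group %||% rep("all", nrow(inc))
  purrr::map_dfr(split(seq_len(nrow(inc)), group), function(idx) {
    tibble::tibble(time = grid, incidence = colMeans(inc[idx, , drop = FALSE]))
  }, .id = "group")
}

#' Out-of-bag concordance of a forest
#'
#' Harrell concordance over comparable subject pairs, using the OOB ensemble
#' mortality as the risk score. Subjects never out of bag are excluded with
#' a warning. The OOB prediction error is `1 - oob_cindex`.
#'
#' @param object An `rsf` forest.
#' @return Concordance in `[0, 1]`.
#' @export
oob_cindex <- function(object) {
  mort <- predict(object, type = "mortality", oob = TRUE)
  if (anyNA(mort))
    warn(sprintf("%d subject(s) were never out of bag and are excluded",
                 sum(is.na(mort))))
  cc <- cpp_cindex(object$time, object$event, mort)
  if (is.na(cc))
    abort("no comparable pairs; concordance undefined",
          class = "riskforest_undefined_error")
  cc
}

#' Harrell concordance index
#'
#' A pair (i, j) is usable when i is observed to fail before j; it counts as
#' concordant when the earlier failure carries the higher risk score (ties
#' in the score count 1/2). Subjects with `NA` risk are excluded.
#'
#' @param time,event Follow-up times and event indicators.
#' @param risk Risk scores (higher = expected earlier failure).
#' @return Concordance in `[0, 1]`.
#' @export
harrell_cindex <- function(time, event, risk) {
  cpp_cindex(as.numeric(time), as.integer(event), as.numeric(risk))
}

#' Minimal depth of each variable
#'
#' Per tree, the depth of the first node split on the variable (root = 0);
#' a variable unused in a tree is assigned that tree's maximum depth plus
#' one so the statistic totally orders the variables. The reported minimal
#' depth is the mean over trees; smaller values indicate variables that
#' split close to the root and are therefore more predictive. For one-hot
#' expanded categorical variables the first split on any of the variable's
#' indicator columns counts.
#'
#' @param object An `rsf` forest.
#' @return Tibble with `variable` and `minimal_depth`, ordered as grown.
#' @export
minimal_depth <- function(object) {
  p <- ncol(object$X)
  total <- numeric(p)
  for (tree in object$trees) {
    used <- tree$var > 0L
    md <- rep.int(max(tree$depth) + 1L, p)
    if (any(used)) {
      first <- tapply(tree$depth[used], tree$var[used], min)
      md[as.integer(names(first))] <- first
    }
    total <- total + md
  }
  col_md <- total / length(object$trees)
  tibble::tibble(variable = object$vars,
                 minimal_depth = vapply(object$vars, function(v)
                   min(col_md[object$col_map == v]), numeric(1),
                   USE.NAMES = FALSE))
}

#' Permutation variable importance (VIMP)
#'
#' The drop in OOB concordance when a variable's values are permuted among
#' each tree's out-of-bag subjects: `VIMP(v) = c_oob - mean over reps of
#' c_oob(v permuted)`. Larger values indicate more predictive variables; a
#' constant column is invariant under permutation and scores exactly zero.
#' Each variable gets a fixed sub-seed derived from `seed`, so importance is
#' reproducible variable by variable.
#'
#' @param object An `rsf` forest.
#' @param n_reps Permutation replicates averaged per variable.
#' @param seed Integer seed (default: the forest seed).
#' @return Tibble with `variable` and `vimp`.
#' @export
permutation_vimp <- function(object, n_reps = NULL, seed = NULL) {
  n_reps <- n_reps %||% object$config$vimp_reps
  seed <- seed %||% object$config$seed
  c_orig <- oob_cindex(object)
  p <- ncol(object$X)
  term_mort <- rowSums(object$chf)
  col_vimp <- vapply(seq_len(p), function(v) {
    set.seed(derive_seed(seed, paste0("vimp_", v)))
    c_perm <- vapply(seq_len(n_reps), function(r) {
      mort <- cpp_oob_mortality_permuted(object$trees, term_mort, object$Xt,
                                         object$inbag, v)
      cpp_cindex(object$time, object$event, mort)
    }, numeric(1))
    c_orig - mean(c_perm)
  }, numeric(1))
  tibble::tibble(variable = object$vars,
                 vimp = vapply(object$vars, function(v)
                   sum(col_vimp[object$col_map == v]), numeric(1),
                   USE.NAMES = FALSE))
}

#' Rank variables by minimal depth and VIMP
#'
#' @param object An `rsf` forest.
#' @param vimp Optional precomputed [permutation_vimp()] table.
#' @return Tibble with `variable`, `minimal_depth`, `vimp`, `md_rank`
#'   (1 = smallest minimal depth) and `vimp_rank` (1 = largest VIMP),
#'   ordered by minimal depth.
#' @export
rank_variables <- function(object, vimp = NULL) {
  md <- minimal_depth(object)
  vi <- vimp %||% permutation_vimp(object)
  dplyr::left_join(md, vi, by = "variable") %>%
    dplyr::mutate(
      md_rank = rank(.data$minimal_depth, ties.method = "first"),
      vimp_rank = rank(-.data$vimp, ties.method = "first")
    ) %>%
    dplyr::arrange(.data$md_rank)
}
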