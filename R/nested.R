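#' Nested-model OOB error curve
#'
#' Fits a sequence of forests on the top-1, top-2, ..., top-K variables of a
#' supplied ordering (typically minimal-depth ascending) and records each
#' model's OOB error `e_k = 1 - c-index`. The null model's error is fixed at
#' 0.5, so the first drop error is `0.5 - e_1`.
#'
#' @param data Modelling frame (see [grow_forest()]).
#' @param ordered_vars Variables in rank order, best first.
#' @param config A [forest_config()]; each nested fit derives its own seed
#'   from `config$seed` and, when `config$mtry` is `NULL`, uses
#'   `ceiling(sqrt(k))` candidate variables.
#' @param time,event Column names.
#' @return A `nested_curve`: tibble with `k`, `variable`, `cindex`, `error`
#'   and `drop_error`, with the null error stored in
#'   `attr(, "null_error")`.
#' @export
nested_error_curve <- function(data, ordered_vars, config = forest_config(),
                               time = "time_years", event = "event") {
  if (length(ordered_vars) == 0)
    abort("empty variable ordering", class = "riskforest_config_error")
  errors <- vapply(seq_along(ordered_vars), function(k) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("nested_", k))
    fit <- grow_forest(data, ordered_vars[seq_len(k)], cfg,
                       time = time, event = event)
    1 - oob_cindex(fit)
  }, numeric(1))
  new_nested_curve(ordered_vars, errors)
}

new_nested_curve <- function(vars, errors, null_error = 0.5) {
  curve <- tibble::tibble(
    k = seq_along(vars), variable = vars,
    cindex = 1 - errors, error = errors,
    drop_error = c(null_error, errors[-length(errors)]) - errors
  )
  structure(curve, null_error = null_error,
            class = c("nested_curve", class(curve)))
}

#' Drop-error rates of a nested error curve
#'
#' The drop error of the k-th ranked variable is the decrease in nested-model
#' OOB error when it enters: `d_k = e_{k-1} - e_k`, with `e_0 = 0.5` for the
#' null model. Drops can be negative when a variable worsens the model. The
#' telescoping identity `0.5 - e_k = sum_{j<=k} d_j` holds exactly.
#'
#' @param curve A `nested_curve`, or a bare numeric vector of nested errors
#'   `e_1..e_K` (e.g. a published error column).
#' @param null_error Error of the null model (0.5 by convention).
#' @return Numeric vector of drop errors `d_1..d_K`.
#' @export
drop_error_rates <- function(curve, null_error = 0.5) {
  e <- if (inherits(curve, "nested_curve")) curve$error else as.numeric(curve)
  c(null_error, e[-length(e)]) - e
}

#' @exportS3Method generics::tidy
tidy.nested_curve <- function(x, ...) tibble::as_tibble(x)
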