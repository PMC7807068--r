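# internal helpers

# Deterministic stage seed derived from a master seed and a label, kept below
# .Machine$integer.max so it is always a valid set.seed() argument.
derive_seed <- function(seed, key) {
  codes <- utf8ToInt(as.character(key))
  h <- sum(codes * seq_along(codes))
  as.integer((as.double(seed) %% 2147483647 * 48271 + h * 1009) %% 2147483587)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_binary <- function(x, what) {
  if (!all(x %in% c(0, 1)))
    abort(paste0(what, " must be coded 0/1"), class = "riskforest_validation_error")
  invisible(x)
}

# one-hot expansion of non-numeric columns; numeric columns pass through.
# Returns a numeric matrix plus a map from matrix column -> source variable.
build_design <- function(data, vars, levels_map = NULL) {
  cols <- list()
  map <- character(0)
  levels_out <- list()
  for (v in vars) {
    x <- data[[v]]
    if (is.null(x))
      abort(paste0("variable '", v, "' not found"),
            class = "riskforest_config_error")
    if (is.numeric(x)) {
      cols[[v]] <- as.numeric(x)
      map <- c(map, setNames(v, v))
    } else {
      x <- as.character(x)
      lev <- if (!is.null(levels_map) && !is.null(levels_map[[v]]))
        levels_map[[v]] else sort(unique(x))
      if (!all(x %in% lev))
        abort(paste0("unseen level in variable '", v, "'"),
              class = "riskforest_prediction_error")
      levels_out[[v]] <- lev
      for (l in lev) {
        nm <- paste0(v, ".", l)
        cols[[nm]] <- as.numeric(x == l)
        map <- c(map, setNames(v, nm))
      }
    }
  }
  X <- do.call(cbind, cols)
  storage.mode(X) <- "double"
  list(X = X, map = map, levels = levels_out)
}
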