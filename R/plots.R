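#' @exportS3Method ggplot2::autoplot
autoplot.stage2_selection <- function(object, ...) {
  rk <- object$ranking
  ggplot2::ggplot(rk, ggplot2::aes(x = .data$md_rank, y = .data$vimp_rank,
                                   colour = .data$selected)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "red") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$variable),
                       size = 2.5, vjust = -0.8, show.legend = FALSE) +
    ggplot2::labs(x = "Minimal-depth rank", y = "VIMP rank",
                  colour = "Selected",
                  title = "Agreement of minimal depth and VIMP rankings") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.nested_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$cindex)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Variables in nested model (minimal-depth order)",
                  y = "OOB c-index") +
    ggplot2::theme_minimal()
}

#' Cumulative-incidence curves by group
#'
#' Plots the ensemble predicted cumulative breast-cancer incidence averaged
#' within groups (e.g. genotype or lifestyle categories), the display used
#' to choose risk genotypes and lifestyle cutoffs.
#'
#' @param object An `rsf` forest.
#' @param newdata Data frame of predictors (default training data).
#' @param group Grouping vector of length `nrow(newdata)`.
#' @return A ggplot.
#' @export
plot_cumulative_incidence <- function(object, newdata = NULL, group = NULL) {
  df <- ensemble_incidence(object, newdata, group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$incidence,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Years of follow-up",
                  y = "Predicted cumulative incidence", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.joint_effect <- function(object, ...) {
  df <- tibble::as_tibble(object) %>%
    dplyr::filter(!is.na(.data$hr)) %>%
    dplyr::mutate(row = paste0(.data$stratum, ": score ", .data$level))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hr,
                                   y = stats::reorder(.data$row,
                                                      dplyr::row_number()))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_point(shape = 15, size = 3, colour = "steelblue") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
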