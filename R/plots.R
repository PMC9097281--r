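#' Plot a PMF profile
#'
#' Free energy against the normalised string coordinate, with the
#' 4-subgroup standard error as a shaded band and the transition-state
#' window marked.
#'
#' @param object a `pmf_profile`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pmf_profile
#' @export
autoplot.pmf_profile <- function(object, ...) {
  tb <- object$profile
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$arc, y = .data$dG)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$dG - .data$se,
                                      ymax = .data$dG + .data$se),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_vline(xintercept = tb$arc[object$ts_window],
                        linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "string coordinate", y = "free energy",
                  title = sprintf("PMF along the unbinding path (barrier %.2f)",
                                  object$barrier)) +
    ggplot2::theme_minimal()
}

#' Plot a string path in two chosen CVs
#'
#' @param object a `string_path`.
#' @param cv_x,cv_y which CV columns to draw.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot string_path
#' @export
autoplot.string_path <- function(object, cv_x = 1, cv_y = 2, ...) {
  tb <- tibble::tibble(x = object$nodes[, cv_x], y = object$nodes[, cv_y],
                       window = seq_len(nrow(object$nodes)))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(color = .data$window), size = 1.5) +
    ggplot2::labs(x = paste0("CV ", cv_x), y = paste0("CV ", cv_y),
                  title = sprintf("string (iteration %d)", object$iteration)) +
    ggplot2::theme_minimal()
}

#' Plot an MLTSA feature analysis
#'
#' Replica-averaged global-mean accuracy drop (MLP) and feature
#' importance (GBDT) per feature, with correlated features coloured by
#' their mixing coefficient alpha and uncorrelated features in black ---
#' the standard sensitivity/specificity comparison of the two rankings.
#'
#' @param object an `mltsa_report`.
#' @param ... unused.
#' @return A ggplot object (two facets: accuracy drop, importance).
#' @method autoplot mltsa_report
#' @export
autoplot.mltsa_report <- function(object, ...) {
  tb <- tidy(object)
  long <- tidyr::pivot_longer(tb, c("mean_drop", "mean_importance"),
                              names_to = "measure", values_to = "value")
  long$measure <- dplyr::recode(long$measure,
                                mean_drop = "MLP accuracy drop",
                                mean_importance = "GBDT feature importance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = .data$value)) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, !.data$correlated),
                        color = "black", size = 0.8, alpha = 0.6) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$correlated),
                        ggplot2::aes(color = .data$alpha * 100), shape = 4,
                        size = 2.5, stroke = 1.2) +
    ggplot2::scale_color_gradient(low = "blue", high = "red",
                                  name = "alpha (%)") +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "feature", y = NULL) +
    ggplot2::theme_minimal()
}
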