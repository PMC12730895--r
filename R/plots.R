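#' Plot a ROC curve
#'
#' @param object A `motiscore_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot motiscore_roc
#' @export
autoplot.motiscore_roc <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = 1 - specificity, y = sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_path(linewidth = 0.8, color = "#c0392b") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC (AUC = %.3f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `motiscore_km` from [kaplan_meier()].
#' @param ... Unused.
#' @return A ggplot of the per-group step functions.
#' @method autoplot motiscore_km
#' @export
autoplot.motiscore_km <- function(object, ...) {
  df <- as_tibble(object) %>%
    group_by(group) %>%
    dplyr::group_modify(~ bind_rows(tibble(time = 0, n_risk = max(.x$n_risk),
                                           n_event = 0, n_censor = 0,
                                           survival = 1), .x)) %>%
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = time, y = survival, color = group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_point(data = filter(df, n_censor > 0), shape = 3,
                        show.legend = FALSE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the fitted biomarker weights
#'
#' @param object A `motiscore_fit`.
#' @param ... Unused.
#' @return A ggplot bar chart of the normalized weights.
#' @method autoplot motiscore_fit
#' @export
autoplot.motiscore_fit <- function(object, ...) {
  df <- tibble(biomarker = object$model$selected,
               weight = unname(object$model$weight))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(biomarker, weight),
                                   y = weight)) +
    ggplot2::geom_col(fill = "#2980b9") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Normalized weight (-log10 p)") +
    ggplot2::theme_minimal()
}

#' Overlay ROC curves of several models
#'
#' @param comparison Result of [auc_compare()].
#' @return A ggplot overlaying the curves, labelled by AUC.
#' @export
plot_roc_overlay <- function(comparison) {
  curves <- attr(comparison, "curves")
  df <- bind_rows(imap(curves, ~ mutate(as_tibble(.x), model = .y)))
  labs <- sprintf("%s (AUC %.3f)",
                  comparison$model, comparison$auc)
  names(labs) <- comparison$model
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - specificity, y = sensitivity,
                                   color = model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_path(linewidth = 0.7) +
    ggplot2::scale_color_discrete(labels = labs) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
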