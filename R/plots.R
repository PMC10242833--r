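#' Plot an importance ranking
#'
#' Horizontal bars of mean decrease in accuracy for the top-ranked items —
#' the usual way a forest's feature hierarchy is displayed.
#'
#' @param object An `importance_ranking` from [rf_importance()].
#' @param top_n Number of leading items to show (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.importance_ranking <- function(object, top_n = nrow(object), ...) {
  df <- head(object, top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$item_id, .data$importance)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Mean decrease in accuracy", y = NULL,
                  title = "Feature importance ranking") +
    ggplot2::theme_minimal()
}

#' Plot the accuracy-versus-complexity curve of a selection report
#'
#' Mean cross-validated test AUC and held-out validation AUC against the
#' number of features entering the model, with the optimal (solid) and
#' minimal (dashed) models marked.
#'
#' @param object A `selection_report` from [select_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.selection_report <- function(object, ...) {
  ev <- tidyr::pivot_longer(
    dplyr::select(object$evaluations, "k", test = "test_auc", validation = "val_auc"),
    cols = c("test", "validation"), names_to = "set", values_to = "auc"
  )
  p <- ggplot2::ggplot(ev, ggplot2::aes(x = .data$k, y = .data$auc,
                                        colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$optimal_k, linetype = "solid",
                        colour = "grey40") +
    ggplot2::labs(x = "Number of features", y = "AUC", colour = NULL,
                  title = "Model performance vs. feature count",
                  subtitle = sprintf("optimal k = %d, minimal k = %s",
                                     object$optimal_k, as.character(object$minimal_k))) +
    ggplot2::theme_minimal()
  if (!is.na(object$minimal_k)) {
    p <- p + ggplot2::geom_vline(xintercept = object$minimal_k,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
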