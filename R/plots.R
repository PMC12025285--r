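#' Plot a fitted feature-selection model
#'
#' `type = "weights"` draws the coefficient heatmap (features by time
#' points, one facet per modality; features with all-zero rows are
#' dropped), `type = "trace"` the objective value per iteration.
#'
#' @param object an [hf_fit()].
#' @param type `"weights"` or `"trace"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hf_fit <- function(object, type = c("weights", "trace"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    df <- tibble::tibble(iteration = seq_along(object$objective_trace) - 1,
                         objective = object$objective_trace)
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$objective)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "iteration", y = "objective",
                      title = "Accelerated proximal gradient descent") +
        ggplot2::theme_minimal()
    )
  }
  df <- tidy(object) |>
    dplyr::group_by(.data$modality, .data$feature) |>
    dplyr::filter(any(.data$selected)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$timepoint,
                                   factor(.data$feature),
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~modality, scales = "free_y") +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "time point", y = "feature",
                  title = "Selected coefficient profiles") +
    ggplot2::theme_minimal()
}

#' Plot a cross-validated run
#'
#' `type = "roc"` draws the pooled ROC curve with the chance diagonal,
#' `type = "stability"` the ranked selection-frequency bars per modality.
#'
#' @param object an [hf_cv()].
#' @param type `"roc"` or `"stability"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hf_cv <- function(object, type = c("roc", "stability"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    lab <- sprintf("AUC = %.4f", object$pooled$auc)
    return(
      ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                             colour = "grey60") +
        ggplot2::geom_step() +
        ggplot2::coord_equal() +
        ggplot2::labs(x = "false positive rate", y = "true positive rate",
                      title = "Pooled ROC", subtitle = lab) +
        ggplot2::theme_minimal()
    )
  }
  df <- object$stability
  label_col <- if ("roi" %in% names(df)) "roi" else "feature_name"
  df$label <- df[[label_col]]
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$label, .data$count),
                                   .data$count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~modality, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "folds selected",
                  title = "Feature selection stability") +
    ggplot2::theme_minimal()
}
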