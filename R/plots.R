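#' Plot a cross-validated classification fit
#'
#' `type = "roc"` draws the pooled held-out ROC curve; `type = "scores"`
#' shows each subject's decision score by group (positive scores vote
#' patient).
#'
#' @param object A `dynfc_loocv` object.
#' @param type `"roc"` or `"scores"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dynfc_loocv
#' @export
autoplot.dynfc_loocv <- function(object, type = c("roc", "scores"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    df <- dplyr::arrange(object$roc, .data$sensitivity, dplyr::desc(.data$specificity))
    ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                     y = .data$sensitivity)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_step(linewidth = 0.8) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                    title = sprintf("ROC (AUC = %.4f)", object$auc)) +
      ggplot2::theme_minimal()
  } else {
    df <- tidy(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score,
                                     colour = .data$correct)) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                          colour = "grey60") +
      ggplot2::geom_jitter(width = 0.15, height = 0) +
      ggplot2::labs(x = NULL, y = "Decision score", colour = "Correct") +
      ggplot2::theme_minimal()
  }
}

#' Plot a canonical-network fingerprint
#'
#' Bar chart of how many of the highest-degree (hub) nodes of a signed
#' discriminative network fall in each canonical network.
#'
#' @param fingerprint Tibble `network`, `n_hubs` from
#'   [node_degree_fingerprint()].
#' @return A ggplot object.
#' @export
plot_fingerprint <- function(fingerprint) {
  ggplot2::ggplot(fingerprint,
                  ggplot2::aes(x = stats::reorder(.data$network, .data$n_hubs),
                               y = .data$n_hubs)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Hub nodes") +
    ggplot2::theme_minimal()
}

#' Heatmap of a connectivity matrix
#'
#' @param mat N x N connectivity matrix (static Fisher-z or dynamic
#'   windowed-variability values).
#' @return A ggplot object.
#' @export
plot_connectivity <- function(mat) {
  df <- tidyr::expand_grid(i = seq_len(nrow(mat)), j = seq_len(ncol(mat)))
  df$value <- mat[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Node", y = "Node",
                  fill = attr(mat, "kind") %||% "value") +
    ggplot2::theme_minimal()
}
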