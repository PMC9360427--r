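#' Tidy a cross-validated classification fit
#'
#' @param x A `dynfc_loocv` object.
#' @param ... Unused.
#' @return One row per fold: `subject_id`, `group`, `score`, `predicted`,
#'   `correct`.
#' @method tidy dynfc_loocv
#' @export
tidy.dynfc_loocv <- function(x, ...) {
  dplyr::mutate(x$folds, correct = .data$group == .data$predicted)
}

#' One-row performance summary of a classification fit
#'
#' @param x A `dynfc_loocv` object.
#' @param ... Unused.
#' @return Tibble with n, confusion counts, accuracy, sensitivity,
#'   specificity, AUC and (when computed) the permutation p-value.
#' @method glance dynfc_loocv
#' @export
glance.dynfc_loocv <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$folds),
    tp = x$confusion$tp, fn = x$confusion$fn,
    tn = x$confusion$tn, fp = x$confusion$fp,
    accuracy = x$metrics$accuracy,
    sensitivity = x$metrics$sensitivity,
    specificity = x$metrics$specificity,
    auc = x$auc,
    permutation_p = if (is.null(x$permutation)) NA_real_ else x$permutation$p
  )
}

#' Tidy signed discriminative networks into one edge table
#'
#' @param x A `dynfc_networks` object.
#' @param ... Unused.
#' @return Tibble `feature`, `node_i`, `node_j`, `weight`, `sign`.
#' @method tidy dynfc_networks
#' @export
tidy.dynfc_networks <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$positive, sign = "positive"),
    dplyr::mutate(x$negative, sign = "negative")
  )
}
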