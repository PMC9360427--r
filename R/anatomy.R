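#' Split classifier weights into positive and negative discriminative networks
#'
#' Edges with positive weights push the decision toward the patient class;
#' edges with negative weights push toward controls.  Zero-weight edges are
#' counted but belong to neither network.
#'
#' @param weights Tibble with columns `feature`, `node_i`, `node_j`, `weight`
#'   (e.g. from [discriminative_networks()]), or a named numeric vector of
#'   weights aligned to `edge_index`.
#' @param edge_index Edge index tibble ([edge_index()]); required when
#'   `weights` is a bare vector.
#' @return A `dynfc_networks` list: `positive` and `negative` edge tibbles
#'   (`node_i`, `node_j`, `weight`), and `n_zero`.
#' @export
extract_weight_networks <- function(weights, edge_index = NULL) {
  if (!is.data.frame(weights)) {
    if (is.null(edge_index))
      abort("`edge_index` is required for a bare weight vector.",
            class = "dynfc_invalid_input")
    if (length(weights) != nrow(edge_index))
      abort("`weights` length does not match `edge_index`.",
            class = "dynfc_invalid_input")
    weights <- dplyr::mutate(edge_index, weight = as.numeric(weights))
  }
  stopifnot(all(c("node_i", "node_j", "weight") %in% names(weights)))
  structure(list(
    positive = dplyr::filter(weights, .data$weight > 0),
    negative = dplyr::filter(weights, .data$weight < 0),
    n_zero = sum(weights$weight == 0)
  ), class = "dynfc_networks")
}

#' @export
print.dynfc_networks <- function(x, ...) {
  cat(sprintf(
    "Discriminative networks: %d positive-weight, %d negative-weight, %d zero-weight edges\n",
    nrow(x$positive), nrow(x$negative), x$n_zero))
  invisible(x)
}

#' Fit the anatomy model and return signed discriminative networks
#'
#' The cross-validated folds each carry their own weight vector; for network
#' anatomy a single vector is needed.  `method = "refit"` (default) selects
#' features on the full sample and refits the linear classifier once on all
#' subjects — the "anatomy model".  `method = "consensus"` instead averages
#' per-fold weights over features selected in at least half of the LOOCV
#' folds of `report`, a robustness companion to the refit.
#'
#' @inheritParams classify_loocv
#' @param method `"refit"` or `"consensus"`.
#' @param report A `dynfc_loocv` object; required for `"consensus"`.
#' @return A `dynfc_networks` object (see [extract_weight_networks()]) with
#'   the full signed weight table attached as attribute `"weights"`.
#' @export
discriminative_networks <- function(features, cost = 1,
                                    selection_threshold = 0.01,
                                    positive_class = "patient",
                                    method = c("refit", "consensus"),
                                    report = NULL) {
  method <- match.arg(method)
  idx <- attr(features, "edge_index")
  if (is.null(idx))
    abort("`features` carries no edge index.", class = "dynfc_invalid_input")
  X <- features_matrix(features)

  if (method == "refit") {
    y <- droplevels(factor(features$group))
    pos <- y == positive_class
    res <- t_stat_matrix(X[pos, , drop = FALSE], X[!pos, , drop = FALSE])
    sel <- which(res$p < selection_threshold)
    if (length(sel) == 0L) {
      warn("no feature passed the filter; using all features.",
           class = "dynfc_empty_selection")
      sel <- seq_len(ncol(X))
    }
    fit <- fit_linear_svm(X[, sel, drop = FALSE], y, cost, positive_class)
    w <- setNames(fit$weights, colnames(X)[sel])
  } else {
    if (is.null(report) || !inherits(report, "dynfc_loocv"))
      abort("`method = \"consensus\"` needs a `report` from classify_loocv().",
            class = "dynfc_invalid_input")
    n_folds <- length(report$fold_selection)
    counts <- table(unlist(report$fold_selection))
    keep <- as.integer(names(counts)[counts >= n_folds / 2])
    if (length(keep) == 0L)
      abort("no feature was selected in at least half of the folds.",
            class = "dynfc_empty_selection")
    w <- vapply(keep, function(k) {
      fname <- colnames(X)[k]
      vals <- unlist(lapply(report$fold_weights, function(fw) fw[fname]))
      mean(vals, na.rm = TRUE)
    }, numeric(1L))
    names(w) <- colnames(X)[keep]
  }

  wt <- dplyr::inner_join(idx,
    tibble::tibble(feature = names(w), weight = unname(w)), by = "feature")
  nets <- extract_weight_networks(wt)
  attr(nets, "weights") <- wt
  attr(nets, "method") <- method
  nets
}

#' Node degrees, hubs and canonical-network fingerprint of a signed network
#'
#' Degree is the number of discriminative edges incident to a node.  The
#' `k` highest-degree nodes (ties broken by ascending node id, so the list is
#' reproducible) are the hubs; their counts per canonical network form the
#' fingerprint.
#'
#' @param edges Edge tibble with `node_i`, `node_j` (one signed network, e.g.
#'   `net$positive`).
#' @param labels Atlas label tibble (`node_id`, `network`), e.g.
#'   [toy_atlas_labels()] or [read_atlas_labels()].
#' @param k Number of hub nodes to report.
#' @return List with `degree` (all incident nodes), `hubs` (top-k with
#'   labels) and `fingerprint` (per-network hub counts, summing to the number
#'   of hubs reported).
#' @export
node_degree_fingerprint <- function(edges, labels, k = 25L) {
  if (k < 1L) abort("`k` must be >= 1.", class = "dynfc_invalid_input")
  stopifnot(all(c("node_i", "node_j") %in% names(edges)),
            all(c("node_id", "network") %in% names(labels)))
  nodes <- c(edges$node_i, edges$node_j)
  deg <- tibble::tibble(node_id = as.integer(names(table(nodes))),
                        degree = as.integer(table(nodes)))
  missing <- setdiff(deg$node_id, labels$node_id)
  if (length(missing) > 0L)
    abort(sprintf("no atlas label for node(s): %s",
                  paste(missing, collapse = ", ")),
          class = "dynfc_labeling_error")
  deg <- dplyr::arrange(deg, dplyr::desc(.data$degree), .data$node_id)
  hubs <- dplyr::left_join(head(deg, k), labels, by = "node_id")
  fingerprint <- dplyr::count(hubs, .data$network, name = "n_hubs",
                              sort = TRUE)
  list(degree = deg, hubs = hubs, fingerprint = fingerprint)
}

#' Toy canonical-network atlas labels
#'
#' Assigns each node to one of the canonical large-scale networks in a
#' deterministic round-robin, for demonstrations and tests.  Real analyses
#' should supply their atlas's assignment via [read_atlas_labels()].
#'
#' @param n_nodes Number of nodes to label.
#' @return Tibble `node_id`, `network`.
#' @export
toy_atlas_labels <- function(n_nodes) {
  tibble::tibble(
    node_id = seq_len(n_nodes),
    network = rep_len(canonical_networks, n_nodes)
  )
}
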