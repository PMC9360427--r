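#' Vectorize the upper triangle of a symmetric connectivity matrix
#'
#' Returns the N(N-1)/2 strictly-upper-triangle entries in row-major order
#' (edge (1,2), (1,3), ..., (1,N), (2,3), ...), the fixed feature order used
#' throughout the package, so classifier weights map deterministically back
#' to node pairs.  A 268-node matrix yields 268 * 267 / 2 = 35,778 features.
#'
#' @param mat Symmetric N x N matrix.
#' @param tol Maximum allowed |mat - t(mat)| before the matrix is rejected as
#'   asymmetric.
#' @return Named numeric vector of length N(N-1)/2 with attribute
#'   `"edge_index"`, a tibble mapping each feature to its node pair
#'   (`feature`, `node_i`, `node_j`).
#' @seealso [unvectorize_upper()]
#' @export
vectorize_upper <- function(mat, tol = 1e-8) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (ncol(mat) != n)
    abort("`mat` must be square.", class = "dynfc_invalid_matrix")
  if (max(abs(mat - t(mat))) > tol)
    abort("`mat` is asymmetric beyond tolerance.", class = "dynfc_invalid_matrix")
  idx <- edge_index(n)
  v <- mat[cbind(idx$node_i, idx$node_j)]
  names(v) <- idx$feature
  attr(v, "edge_index") <- idx
  v
}

#' Rebuild a symmetric matrix from an upper-triangle feature vector
#'
#' @param v Feature vector in the order produced by [vectorize_upper()].
#' @param n Number of nodes; inferred from `length(v)` when missing.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
unvectorize_upper <- function(v, n = NULL) {
  if (is.null(n)) n <- as.integer(round((1 + sqrt(1 + 8 * length(v))) / 2))
  if (n * (n - 1) / 2 != length(v))
    abort("`length(v)` is not a triangular number matching `n`.",
          class = "dynfc_invalid_input")
  idx <- edge_index(n)
  m <- matrix(0, n, n)
  m[cbind(idx$node_i, idx$node_j)] <- v
  m + t(m)
}

#' Edge-feature index for an N-node network
#'
#' @param n Number of nodes.
#' @return Tibble `feature` (label `e<i>_<j>`), `node_i`, `node_j` covering
#'   the strictly-upper triangle in row-major order.
#' @export
edge_index <- function(n) {
  p <- upper_pairs(n)
  p$feature <- sprintf("e%d_%d", p$node_i, p$node_j)
  p[, c("feature", "node_i", "node_j")]
}

#' Build a subjects-by-edges feature table
#'
#' Vectorizes each subject's connectivity matrix into the fixed edge-feature
#' order and stacks subjects in cohort (manifest) order.
#'
#' @param conn_tbl A `dynfc_conn_tbl` from [compute_connectivity()] (columns
#'   `subject_id`, `group`, `conn`).
#' @return A `dynfc_features` tibble: `subject_id`, `group`, then one numeric
#'   column per edge feature.  The edge index is attached as attribute
#'   `"edge_index"` and the connectivity kind as `"kind"`.
#' @export
edge_features <- function(conn_tbl) {
  stopifnot(all(c("subject_id", "group", "conn") %in% names(conn_tbl)))
  mats <- conn_tbl$conn
  n <- nrow(mats[[1L]])
  idx <- edge_index(n)
  X <- t(vapply(mats, function(m) m[cbind(idx$node_i, idx$node_j)],
                numeric(nrow(idx))))
  colnames(X) <- idx$feature
  out <- tibble::tibble(subject_id = conn_tbl$subject_id, group = conn_tbl$group)
  out <- dplyr::bind_cols(out, tibble::as_tibble(X))
  attr(out, "edge_index") <- idx
  attr(out, "kind") <- attr(conn_tbl, "kind")
  class(out) <- c("dynfc_features", class(out))
  out
}

features_matrix <- function(features) {
  cols <- setdiff(names(features), c("subject_id", "group"))
  as.matrix(features[, cols, drop = FALSE])
}

#' Pooled-variance two-sample t-test
#'
#' Student's two-tailed t with pooled variance and df = n_x + n_y - 2, the
#' classical form used both for demographics checks and as the univariate
#' edge filter.  Degenerate inputs follow a fixed policy: zero pooled
#' variance with equal means gives t = 0, p = 1; zero pooled variance with
#' unequal means gives p = 0 (perfect separation sentinel) with a warning.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return Tibble with one row: `t`, `df`, `p`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p = 0.0213
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    abort("each group needs at least 2 values.", class = "dynfc_invalid_input")
  res <- t_stat_matrix(matrix(x, ncol = 1L), matrix(y, ncol = 1L))
  tibble::tibble(t = res$t, df = res$df, p = res$p)
}

# vectorized pooled t over columns of two matrices (same columns, different rows)
t_stat_matrix <- function(X, Y) {
  nx <- nrow(X); ny <- nrow(Y)
  df <- nx + ny - 2L
  mx <- colMeans(X); my <- colMeans(Y)
  ssx <- colSums(X * X) - nx * mx * mx
  ssy <- colSums(Y * Y) - ny * my * my
  sp2 <- (ssx + ssy) / df
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  d <- mx - my
  t <- d / se
  p <- 2 * pt(-abs(t), df)
  zero_var <- sp2 <= 0 | !is.finite(t)
  if (any(zero_var)) {
    eq <- zero_var & abs(d) <= .Machine$double.eps^0.5
    t[eq] <- 0; p[eq] <- 1
    sep <- zero_var & !eq
    if (any(sep)) {
      warn("zero pooled variance with unequal means: p set to 0.",
           class = "dynfc_degenerate_t")
      t[sep] <- sign(d[sep]) * Inf
      p[sep] <- 0
    }
  }
  list(t = unname(t), df = df, p = unname(p))
}

#' Edge-wise group comparison across all features
#'
#' Runs the pooled two-sample t-test ([two_sample_t()]) on every edge feature,
#' patients minus controls.
#'
#' @param features A `dynfc_features` tibble (or any tibble with `group` plus
#'   numeric feature columns).
#' @param positive_class Group treated as the first sample (its mean enters
#'   with positive sign).
#' @return Tibble with one row per feature: `feature`, `node_i`, `node_j`
#'   (when an edge index is available), `t`, `p`.
#' @export
edge_t_table <- function(features, positive_class = "patient") {
  y <- features$group
  if (length(unique(y)) < 2L)
    abort("both groups must be present.", class = "dynfc_invalid_design")
  X <- features_matrix(features)
  res <- t_stat_matrix(X[y == positive_class, , drop = FALSE],
                       X[y != positive_class, , drop = FALSE])
  out <- tibble::tibble(feature = colnames(X), t = res$t, p = res$p)
  idx <- attr(features, "edge_index")
  if (!is.null(idx)) out <- dplyr::left_join(out, idx, by = "feature")[,
    c("feature", "node_i", "node_j", "t", "p")]
  out
}

#' Univariate feature selection by edge-wise t-test
#'
#' Retains features whose two-tailed pooled-t p-value is strictly below the
#' threshold (0.01 by default; 0.5 and 0.001 are the usual sensitivity
#' settings).  This is a filter, not an inference: p-values are not adjusted
#' for multiplicity, and ties at exactly p = threshold are excluded.
#'
#' @inheritParams edge_t_table
#' @param threshold Selection threshold on the per-feature p-value.
#' @return A `dynfc_selection` tibble: `feature`, `t`, `p`, `selected`, with
#'   the threshold attached as attribute.
#' @export
select_edge_features <- function(features, threshold = 0.01,
                                 positive_class = "patient") {
  if (threshold <= 0 || threshold > 1)
    abort("`threshold` must lie in (0, 1].", class = "dynfc_invalid_input")
  tt <- edge_t_table(features, positive_class)
  tt$selected <- tt$p < threshold
  attr(tt, "threshold") <- threshold
  class(tt) <- c("dynfc_selection", class(tt))
  tt
}

#' Pearson chi-square statistic for a 2 x 2 contingency table
#'
#' Classical homogeneity chi-square, sum of (O - E)^2 / E over the four
#' cells, without continuity correction — the demographics check used for
#' gender balance (e.g. 33/38 female/male patients vs 26/45 controls gives
#' chi-square 1.421).
#'
#' @param table 2 x 2 matrix of counts; rows = groups, columns = categories.
#' @return Tibble with `chi2`, `df`, `p`.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    abort("`table` must be 2 x 2.", class = "dynfc_invalid_table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    abort("all row and column marginals must be positive.",
          class = "dynfc_invalid_table")
  ct <- stats::chisq.test(table, correct = FALSE)
  tibble::tibble(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value)
}
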