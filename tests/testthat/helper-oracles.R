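# Independent brute-force oracles used across the suite.  These deliberately
# recompute quantities with naive loops / closed forms, never through the
# package's own code paths.

# plain Pearson correlation matrix via explicit sums
naive_cor <- function(x) {
  n <- ncol(x)
  out <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
    r <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    out[i, j] <- out[j, i] <- r
  }
  out
}

# weighted Pearson correlation with normalized weights, explicit formula
naive_weighted_cor <- function(x, w) {
  w <- w / sum(w)
  n <- ncol(x)
  m <- colSums(w * x)
  out <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    xi <- x[, i] - m[i]; xj <- x[, j] - m[j]
    cij <- sum(w * xi * xj)
    out[i, j] <- out[j, i] <- cij / sqrt(sum(w * xi^2) * sum(w * xj^2))
  }
  out
}

naive_fisher_z <- function(r, eps = 1e-7) atanh(pmin(pmax(r, -(1 - eps)), 1 - eps))

# window-by-window recomputation of the windowed-z standard deviation
naive_dynamic_sd <- function(x, w, s, weights) {
  Tn <- nrow(x)
  starts <- seq(1, Tn - w + 1, by = s)
  zs <- lapply(starts, function(st) {
    naive_fisher_z(naive_weighted_cor(x[st:(st + w - 1), , drop = FALSE], weights))
  })
  n <- ncol(x)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- vapply(zs, function(z) z[i, j], numeric(1))
    out[i, j] <- out[j, i] <- stats::sd(v)
  }
  out
}

# AUC by exhaustive pair counting, ties counted one half
naive_auc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# small cohort tibble built by hand (no generator involved)
manual_cohort <- function(mats, groups) {
  tibble::tibble(
    subject_id = sprintf("s%02d", seq_along(mats)),
    group = factor(groups, levels = c("control", "patient")),
    series = mats
  )
}

# separable feature tibble: two Gaussian blobs
blob_features <- function(n_per_group = 10, n_feat = 5, delta = 20, sd = 0.1,
                          seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(
      matrix(rnorm(n_per_group * n_feat, 0, sd), n_per_group),
      matrix(rnorm(n_per_group * n_feat, delta, sd), n_per_group)
    )
  })
  colnames(X) <- sprintf("e1_%d", seq_len(n_feat) + 1)
  out <- tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(2 * n_per_group)),
    group = factor(rep(c("control", "patient"), each = n_per_group),
                   levels = c("control", "patient"))
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(X))
  attr(out, "edge_index") <- tibble::tibble(
    feature = colnames(X), node_i = 1L, node_j = seq_len(n_feat) + 1L)
  class(out) <- c("dynfc_features", class(out))
  out
}
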