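test_that("upper-triangle vectorization has the canonical dimension and order", {
  # 268 nodes -> 268 * 267 / 2 = 35,778 edge features
  v268 <- vectorize_upper(matrix(0, 268, 268))
  expect_length(v268, 35778)

  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 10; m[1, 3] <- m[3, 1] <- 20; m[2, 3] <- m[3, 2] <- 30
  v <- vectorize_upper(m)
  expect_equal(as.numeric(v), c(10, 20, 30))
  expect_equal(names(v), c("e1_2", "e1_3", "e2_3"))

  expect_error(vectorize_upper(matrix(1:9, 3, 3)), class = "dynfc_invalid_matrix")
  expect_error(vectorize_upper(matrix(0, 2, 3)), class = "dynfc_invalid_matrix")
})

test_that("vectorize / unvectorize round-trips random symmetric matrices", {
  set.seed(13)
  for (n in c(3, 7, 12)) {
    m <- matrix(rnorm(n * n), n, n)
    m <- m + t(m); diag(m) <- 0
    expect_equal(unvectorize_upper(vectorize_upper(m)), m)
  }
})

test_that("pooled two-sample t matches both the closed form and t.test", {
  res <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.6742, tolerance = 1e-4)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.02131, tolerance = 1e-4)

  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    ref <- t.test(x, y, var.equal = TRUE)
    got <- two_sample_t(x, y)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    # antisymmetry
    swapped <- two_sample_t(y, x)
    expect_equal(swapped$t, -got$t, tolerance = 1e-12)
    expect_equal(swapped$p, got$p, tolerance = 1e-12)
  }
})

test_that("degenerate two-sample inputs follow the fixed policy", {
  same <- two_sample_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_warning(sep <- two_sample_t(c(1, 1, 1), c(5, 5, 5)),
                 class = "dynfc_degenerate_t")
  expect_equal(sep$p, 0)
  expect_error(two_sample_t(1, c(1, 2)), class = "dynfc_invalid_input")
})

test_that("edge-wise t table matches per-feature t.test on every column", {
  f <- blob_features(n_per_group = 6, n_feat = 4, delta = 0.5, sd = 1, seed = 3)
  tt <- edge_t_table(f)
  X <- as.matrix(f[, tt$feature])
  pat <- f$group == "patient"
  for (k in seq_len(ncol(X))) {
    ref <- t.test(X[pat, k], X[!pat, k], var.equal = TRUE)
    expect_equal(tt$t[k], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(tt$p[k], ref$p.value, tolerance = 1e-10)
  }
  expect_error(edge_t_table(dplyr::filter(f, group == "control")),
               class = "dynfc_invalid_design")
})

test_that("selection is strict, monotone in the threshold, and supports the usual levels", {
  f <- blob_features(n_per_group = 8, n_feat = 30, delta = 0.3, sd = 1, seed = 9)
  sel_all <- select_edge_features(f, threshold = 1)
  expect_true(all(sel_all$selected == (sel_all$p < 1)))

  masks <- lapply(c(0.001, 0.01, 0.5), function(th)
    select_edge_features(f, threshold = th)$selected)
  expect_true(all(masks[[1]] <= masks[[2]]))  # mask(0.001) subset of mask(0.01)
  expect_true(all(masks[[2]] <= masks[[3]]))
  expect_error(select_edge_features(f, threshold = 0), class = "dynfc_invalid_input")
})

test_that("a planted near-separable feature is the only selection at a tiny threshold", {
  set.seed(31)
  n <- 20; p <- 100
  X <- matrix(rnorm(n * 2 * p), n * 2, p)
  X[21:40, 57] <- rnorm(n, mean = 10, sd = 0.1)
  X[1:20, 57] <- rnorm(n, mean = 0, sd = 0.1)
  colnames(X) <- sprintf("e1_%d", 2:(p + 1))
  f <- tibble::tibble(subject_id = sprintf("s%02d", 1:40),
                      group = factor(rep(c("control", "patient"), each = 20),
                                     levels = c("control", "patient")))
  f <- dplyr::bind_cols(f, tibble::as_tibble(X))
  sel <- select_edge_features(f, threshold = 1e-6)
  expect_equal(which(sel$selected), 57)
})

test_that("under null features the selected fraction tracks the threshold", {
  set.seed(8)
  n_feat <- 600
  X <- matrix(rnorm(30 * n_feat), 30, n_feat)
  colnames(X) <- sprintf("e1_%d", 2:(n_feat + 1))
  f <- tibble::tibble(subject_id = sprintf("s%02d", 1:30),
                      group = factor(rep(c("control", "patient"), each = 15),
                                     levels = c("control", "patient")))
  f <- dplyr::bind_cols(f, tibble::as_tibble(X))
  for (th in c(0.05, 0.2)) {
    frac <- mean(select_edge_features(f, threshold = th)$selected)
    expect_lt(abs(frac - th), 3 * sqrt(th * (1 - th) / n_feat))
  }
})

test_that("the 2x2 chi-square matches hand computation and the gender table", {
  # the study's gender table: 33/38 female/male patients vs 26/45 controls
  gender <- matrix(c(33, 26, 38, 45), nrow = 2)
  expect_equal(round(pearson_chi2(gender)$chi2, 3), 1.421)

  expect_equal(pearson_chi2(matrix(c(10, 10, 10, 10), 2))$chi2, 0)
  # [[20,10],[10,20]]: E = 15 in every cell, chi2 = 4 * 25/15 = 6.6667
  expect_equal(pearson_chi2(matrix(c(20, 10, 10, 20), 2))$chi2, 20 / 3,
               tolerance = 1e-10)

  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2)), class = "dynfc_invalid_table")
  expect_error(pearson_chi2(matrix(1:6, 2)), class = "dynfc_invalid_table")
})

test_that("feature tables preserve cohort order and map back to node pairs", {
  coh <- simulate_cohort(cohort_config(n_per_group = 3, n_nodes = 6,
                                       n_samples = 80, regime_length = 20,
                                       seed = 4))
  f <- edge_features(compute_connectivity(coh, "static"))
  expect_equal(f$subject_id, coh$subject_id)
  idx <- attr(f, "edge_index")
  expect_equal(nrow(idx), 15)
  expect_true(all(idx$node_i < idx$node_j))
  # feature column k holds matrix entry (i, j) of each subject
  m1 <- compute_connectivity(coh, "static")$conn[[1]]
  expect_equal(unname(unlist(f[1, idx$feature[5]])), m1[idx$node_i[5], idx$node_j[5]])
})
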