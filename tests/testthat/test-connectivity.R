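test_that("window enumeration matches the count formula and orders windows", {
  # 175 samples, w = 50, s = 1: the canonical 126-window configuration
  w126 <- make_windows(175, window_spec(50, 1))
  expect_equal(nrow(w126), 126)
  expect_equal(w126$start, 1:126)
  expect_equal(w126$end, 50:175)

  # single window when w = T
  w1 <- make_windows(40, window_spec(40, 1))
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$start, w1$end), c(1, 40))

  # floor((10 - 4) / 3) + 1 = 3 windows at starts 1, 4, 7 (1-based)
  w3 <- make_windows(10, window_spec(4, 3))
  expect_equal(w3$start, c(1, 4, 7))

  expect_error(make_windows(10, window_spec(11, 1)), class = "dynfc_invalid_window")
})

test_that("taper weights are normalized and reflect the chosen taper", {
  for (spec in list(window_spec(50, 1, "hamming"), window_spec(7, 2, "rectangular"))) {
    wts <- make_windows(100, spec)$weights[[1]]
    expect_equal(sum(wts), 1)
    expect_length(wts, spec$length)
  }
  hw <- make_windows(100, window_spec(50, 1, "hamming"))$weights[[1]]
  expect_gt(hw[25], hw[1])  # cosine taper peaks centrally
  rw <- make_windows(100, window_spec(50, 1, "rectangular"))$weights[[1]]
  expect_equal(rw, rep(1 / 50, 50))
})

test_that("global-signal regression matches an explicit least-squares solve", {
  # 4-sample, 3-node toy vs normal equations
  x <- matrix(c(1, 2, 3, 5,
                2, 1, 4, 3,
                0, 6, 1, 2), ncol = 3)
  g <- rowMeans(x)
  D <- cbind(1, g)
  beta <- solve(t(D) %*% D, t(D) %*% x)
  expect_equal(unname(regress_global_signal(x)), unname(x - D %*% beta),
               tolerance = 1e-12)

  # residuals are uncorrelated with the regressor
  res <- regress_global_signal(x)
  expect_lt(max(abs(crossprod(g - mean(g), res))), 1e-10)
})

test_that("global-signal regression handles shared and orthogonal signals", {
  g <- sin(seq_len(20))
  shared <- cbind(g, g, g)
  expect_lt(max(abs(regress_global_signal(shared))), 1e-12)

  # build a third node exactly uncorrelated with the cross-node mean: with
  # v = alpha * s + u (u orthogonal to s = a + b and centered), cov(v, mean)
  # vanishes when alpha^2 var(s) + alpha var(s) + var(u) = 0
  set.seed(4)
  a <- rnorm(50); b <- rnorm(50)
  s <- a + b
  u <- residuals(lm(rnorm(50, sd = 0.1) ~ s))
  S <- sum((s - mean(s))^2); U <- sum((u - mean(u))^2)
  alpha <- (-S + sqrt(S^2 - 4 * S * U)) / (2 * S)
  v <- alpha * s + u
  x <- cbind(a, b, v)
  gm <- rowMeans(x)
  expect_lt(abs(cor(v, gm)), 1e-10)  # construction check
  res <- regress_global_signal(x)
  expect_equal(res[, 3], v - mean(v), tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(regress_global_signal(matrix(1, 5, 3)),
               class = "dynfc_degenerate_signal")
})

test_that("static connectivity equals the direct-formula computation", {
  set.seed(7)
  x <- matrix(rnorm(6 * 3), 6, 3)
  z <- static_fc(x)
  expect_equal(unname(unclass(z)), naive_fisher_z(naive_cor(x)) - diag(naive_fisher_z(1), 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(diag(z), rep(0, 3), ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(z)))
})

test_that("perfect collinearity gives a finite clipped Fisher z", {
  x <- matrix(rnorm(30), 30, 1)
  m <- cbind(x, 2 * x + 3)
  z <- static_fc(m)
  expect_true(is.finite(z[1, 2]))
  expect_equal(z[1, 2], atanh(1 - 1e-7))
})

test_that("constant columns follow the zero-edge policy with a warning", {
  set.seed(1)
  x <- cbind(rnorm(20), rep(3, 20), rnorm(20))
  expect_warning(z <- static_fc(x), class = "dynfc_constant_node")
  expect_equal(z[1, 2], 0)
  expect_equal(z[2, 3], 0)
  expect_false(z[1, 3] == 0)
})

test_that("windowed correlation matches a brute-force weighted-moment oracle", {
  set.seed(21)
  x <- matrix(rnorm(30 * 2), 30, 2)
  spec <- window_spec(8, 5, "hamming")
  wins <- make_windows(30, spec)
  series <- windowed_fc_series(x, spec)
  expect_length(series, nrow(wins))
  for (k in seq_along(series)) {
    rows <- wins$start[k]:wins$end[k]
    oracle <- naive_fisher_z(naive_weighted_cor(x[rows, , drop = FALSE],
                                                wins$weights[[k]]))
    diag(oracle) <- 0
    expect_equal(unname(unclass(series[[k]])), oracle, tolerance = 1e-12)
  }
})

test_that("a single rectangular full-length window reproduces static connectivity", {
  set.seed(3)
  x <- matrix(rnorm(40 * 4), 40, 4)
  spec <- window_spec(40, 1, "rectangular")
  series <- windowed_fc_series(x, spec)
  expect_length(series, 1)
  expect_equal(unclass(series[[1]]), unclass(static_fc(x)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(dynamic_fc(x, spec), class = "dynfc_invalid_window")
})

test_that("dynamic connectivity is the window-wise sd and detects regime flips", {
  # identical nodes: windowed r is constantly 1 (clipped), sd = 0
  set.seed(5)
  a <- rnorm(60)
  z <- dynamic_fc(cbind(a, a), window_spec(20, 10))
  expect_lt(z[1, 2], 1e-6)  # clipping at |r| = 1 - 1e-7 leaves sub-1e-6 jitter

  # two-regime toy: +c coupling first half, -c second half
  set.seed(9)
  f <- rnorm(120); e1 <- rnorm(120, sd = 0.4); e2 <- rnorm(120, sd = 0.4)
  sgn <- rep(c(1, -1), each = 60)
  x <- cbind(f + e1, sgn * f + e2)
  spec <- window_spec(30, 15, "hamming")
  got <- dynamic_fc(x, spec)
  oracle <- naive_dynamic_sd(x, 30, 15, make_windows(120, spec)$weights[[1]])
  expect_equal(unname(unclass(got)), oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_gt(got[1, 2], 0.5)  # the flip dominates the windowed series
})

test_that("raising the coupling swing raises expected dynamic connectivity", {
  # swing amplitude up => windowed-correlation dispersion up, checked over seeds
  mean_dfc <- function(amp) {
    vals <- vapply(1:6, function(s) {
      withr::with_seed(s, {
        f <- rnorm(150)
        sgn <- rep(rep(c(1, -1), each = 25), 3)
        x <- cbind(sqrt(amp) * f + rnorm(150),
                   sgn * sqrt(amp) * f + rnorm(150))
      })
      dynamic_fc(x, window_spec(50, 5))[1, 2]
    }, numeric(1))
    mean(vals)
  }
  expect_gt(mean_dfc(0.6), mean_dfc(0.15))
})

test_that("connectivity matrices keep symmetry, zero diagonal, non-negative dynamics", {
  set.seed(77)
  for (rep in 1:5) {
    x <- matrix(rnorm(30 * 5), 30, 5)
    zs <- static_fc(x)
    zd <- dynamic_fc(x, window_spec(10, 4))
    for (z in list(zs, zd)) {
      expect_true(isSymmetric(unclass(z)))
      expect_equal(diag(z), rep(0, 5), ignore_attr = TRUE)
    }
    expect_true(all(unclass(zd) >= 0))
  }
})

test_that("cohort-level connectivity tags kind and applies GSR when asked", {
  coh <- simulate_cohort(cohort_config(n_per_group = 3, n_nodes = 6,
                                       n_samples = 80, regime_length = 20,
                                       seed = 2))
  cs <- compute_connectivity(coh, "static", gsr = TRUE)
  expect_s3_class(cs, "dynfc_conn_tbl")
  expect_equal(attr(cs, "kind"), "static")
  expect_true(attr(cs, "gsr"))
  # GSR changes the matrices relative to the raw series
  cs0 <- compute_connectivity(coh, "static", gsr = FALSE)
  expect_gt(max(abs(cs$conn[[1]] - cs0$conn[[1]])), 0.01)
})
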