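#' Sliding-window specification
#'
#' @param length Window length w in samples.
#' @param step Window step s in samples.
#' @param taper `"hamming"` (cosine taper) or `"rectangular"` (uniform).
#' @return A `dynfc_window` list.
#' @details The number of windows over a series of T samples is
#'   `floor((T - w) / s) + 1`.  With the default w = 50 and s = 1, a series of
#'   175 samples yields 126 windows.
#' @export
window_spec <- function(length = 50L, step = 1L, taper = c("hamming", "rectangular")) {
  taper <- match.arg(taper)
  length <- as.integer(length); step <- as.integer(step)
  if (length < 1L) abort("window `length` must be >= 1.", class = "dynfc_invalid_window")
  if (step < 1L) abort("window `step` must be >= 1.", class = "dynfc_invalid_window")
  structure(list(length = length, step = step, taper = taper),
            class = "dynfc_window")
}

#' Enumerate sliding windows over a series
#'
#' @param n_samples Series length T.
#' @param spec A [window_spec()].
#' @return Tibble with one row per window: `window` (1-based index), `start`,
#'   `end` (1-based inclusive sample range) and `weights`, a list column of
#'   per-sample taper weights normalized to sum to 1.
#' @examples
#' nrow(make_windows(175, window_spec(50, 1)))  # 126
#' @export
make_windows <- function(n_samples, spec = window_spec()) {
  stopifnot(inherits(spec, "dynfc_window"))
  w <- spec$length; s <- spec$step
  if (w > n_samples)
    abort(sprintf("window length %d exceeds series length %d.", w, n_samples),
          class = "dynfc_invalid_window")
  n_win <- (n_samples - w) %/% s + 1L
  starts <- 1L + s * (seq_len(n_win) - 1L)
  wts <- taper_weights(w, spec$taper)
  tibble::tibble(
    window = seq_len(n_win),
    start = starts,
    end = starts + w - 1L,
    weights = rep(list(wts), n_win)
  )
}

taper_weights <- function(w, taper) {
  wts <- if (taper == "hamming" && w > 1L) as.numeric(signal::hamming(w)) else rep(1, w)
  wts / sum(wts)
}

fisher_z <- function(r, eps = 1e-7) atanh(pmin(pmax(r, -(1 - eps)), 1 - eps))

# shared post-processing: zero the diagonal; zero-variance nodes give NA
# correlations, which are set to 0 under the fixed-dimension policy
finalize_conn <- function(z, node_ids, warn_constant = TRUE) {
  if (anyNA(z)) {
    if (warn_constant)
      warn("constant node signal(s): affected edges set to 0.",
           class = "dynfc_constant_node")
    z[is.na(z)] <- 0
  }
  diag(z) <- 0
  dimnames(z) <- list(node_ids, node_ids)
  z
}

node_ids_of <- function(x) {
  if (!is.null(colnames(x))) colnames(x) else sprintf("n%03d", seq_len(ncol(x)))
}

#' Regress the global (mean) signal out of every node
#'
#' Computes the cross-node mean time course and replaces each node's signal
#' with its least-squares residual after regressing out that mean together
#' with an intercept.
#'
#' @param x T x N numeric matrix of node signals (one column per node).
#' @return Matrix of the same shape; residual columns are uncorrelated with
#'   the global regressor up to numerical tolerance.
#' @export
regress_global_signal <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L)
    abort("global-signal regression needs at least 3 samples.",
          class = "dynfc_invalid_input")
  g <- rowMeans(x)
  if (sd(g) == 0 && all(apply(x, 2L, sd) == 0))
    abort("all node signals are constant; nothing to regress.",
          class = "dynfc_degenerate_signal")
  res <- lm.fit(cbind(1, g), x)$residuals
  res <- as.matrix(res)
  dimnames(res) <- dimnames(x)
  res
}

#' Static functional connectivity (Fisher-z Pearson correlation)
#'
#' Pearson correlation of every node pair over the full series, Fisher
#' z-transformed (`atanh`, with |r| clipped at 1 - 1e-7 so the transform stays
#' finite under perfect collinearity).  The diagonal is defined as 0.
#'
#' @param x T x N matrix of node signals.
#' @return Symmetric N x N `dynfc_conn` matrix, `kind = "static"`.
#' @export
static_fc <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L)
    abort("static connectivity needs at least 3 samples.",
          class = "dynfc_invalid_input")
  r <- suppressWarnings(cor(x))
  z <- finalize_conn(fisher_z(r), node_ids_of(x))
  structure(z, kind = "static", class = c("dynfc_conn", "matrix", "array"))
}

#' Windowed connectivity series
#'
#' Applies the taper of each sliding window to the samples it covers and
#' computes the weighted Pearson correlation (weighted means, weighted
#' covariances; weights normalized to sum to 1), Fisher z-transformed, one
#' matrix per window.
#'
#' @inheritParams static_fc
#' @param spec A [window_spec()].
#' @return List of symmetric N x N matrices, one per window, in window order.
#' @export
windowed_fc_series <- function(x, spec = window_spec()) {
  x <- as.matrix(x)
  wins <- make_windows(nrow(x), spec)
  ids <- node_ids_of(x)
  warned <- FALSE
  out <- vector("list", nrow(wins))
  for (k in seq_len(nrow(wins))) {
    rows <- wins$start[k]:wins$end[k]
    cw <- suppressWarnings(cov.wt(x[rows, , drop = FALSE], wt = wins$weights[[k]],
                                  cor = TRUE, method = "ML"))
    r <- cw$cor
    if (anyNA(r) && !warned) warned <- TRUE
    out[[k]] <- finalize_conn(fisher_z(r), ids, warn_constant = FALSE)
  }
  if (warned)
    warn("constant node signal(s) within at least one window: affected edges set to 0.",
         class = "dynfc_constant_node")
  out
}

#' Dynamic functional connectivity (sliding-window variability)
#'
#' For each edge, the sample standard deviation (denominator K - 1 over K
#' windows) of the windowed Fisher-z correlation series.  A higher entry means
#' the coupling of that node pair fluctuates more across the scan.
#'
#' @inheritParams windowed_fc_series
#' @return Symmetric non-negative N x N `dynfc_conn` matrix,
#'   `kind = "dynamic"`.
#' @export
dynamic_fc <- function(x, spec = window_spec()) {
  series <- windowed_fc_series(x, spec)
  K <- length(series)
  if (K < 2L)
    abort("dynamic connectivity needs at least 2 windows.",
          class = "dynfc_invalid_window")
  s1 <- Reduce(`+`, series)
  s2 <- Reduce(`+`, lapply(series, function(m) m * m))
  v <- (s2 - s1 * s1 / K) / (K - 1)
  v[v < 0] <- 0  # guard tiny negative rounding
  z <- sqrt(v)
  diag(z) <- 0
  structure(z, kind = "dynamic", class = c("dynfc_conn", "matrix", "array"))
}

#' Compute connectivity for every subject of a cohort
#'
#' @param cohort Tibble with columns `subject_id`, `group` and `series`
#'   (list of T x N matrices), e.g. from [simulate_cohort()] or
#'   [read_cohort()].
#' @param kind `"static"` or `"dynamic"`.
#' @param window A [window_spec()]; used only for dynamic connectivity.
#' @param gsr If `TRUE`, regress the cross-node mean signal out of every node
#'   first ([regress_global_signal()]).
#' @return A `dynfc_conn_tbl` tibble: `subject_id`, `group`, `conn` (list of
#'   N x N matrices); the kind, window and GSR flag are attached as
#'   attributes.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_per_group = 3, n_nodes = 6,
#'                                      n_samples = 60, regime_length = 10))
#' compute_connectivity(coh, "static")
#' @export
compute_connectivity <- function(cohort, kind = c("dynamic", "static"),
                                 window = window_spec(), gsr = FALSE) {
  kind <- match.arg(kind)
  stopifnot(all(c("subject_id", "group", "series") %in% names(cohort)))
  conn <- lapply(cohort$series, function(x) {
    if (gsr) x <- regress_global_signal(x)
    if (kind == "static") static_fc(x) else dynamic_fc(x, window)
  })
  out <- tibble::tibble(subject_id = cohort$subject_id,
                        group = cohort$group, conn = conn)
  attr(out, "kind") <- kind
  attr(out, "window") <- if (kind == "dynamic") window else NULL
  attr(out, "gsr") <- gsr
  class(out) <- c("dynfc_conn_tbl", class(out))
  out
}
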