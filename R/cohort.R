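#' Configuration for a synthetic two-group cohort
#'
#' Bundles and validates all parameters of the regime-switching latent-factor
#' simulator.  The simulator emulates preprocessed (band-limited, nuisance-
#' cleaned) regional BOLD time series for a "patient" and a "control" group
#' whose connectivity may differ on a planted subset of edges, either in the
#' variability of windowed coupling (a dynamic effect) or in mean coupling
#' (a static effect).
#'
#' @param n_per_group Subjects per group.
#' @param n_nodes Number of regions (nodes) per subject.
#' @param n_samples Number of time points T (volumes).
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param dynamic_effect Amplitude (in [0, 0.9], correlation units) of the
#'   regime-switching coupling planted on affected edges in patients.  The
#'   coupling alternates sign across regimes, so it raises the variability of
#'   windowed correlation without shifting the full-series mean correlation.
#' @param static_effect Constant coupling (correlation units, |value| <= 0.9)
#'   planted on affected edges in patients; shifts mean correlation without a
#'   regime-switching component.
#' @param affected_edge_fraction Fraction (0, 1] of edges carrying the planted
#'   effects; the subset is drawn reproducibly from `seed`.  Planted edges
#'   form a node-disjoint matching (so each planted coupling is realizable as
#'   the exact target correlation of its pair), which caps the effective
#'   count at `floor(n_nodes / 2)`.
#' @param global_signal_sd Loading of an optional shared global component in
#'   units of node signal standard deviation (0 disables it).  Each subject's
#'   realized amplitude is log-normally jittered around this value, emulating
#'   the subject-to-subject variation in global fluctuations that makes
#'   global-signal regression consequential in real cohorts.
#' @param global_dynamics_sd Stationary standard deviation of the slow
#'   log-amplitude drift of the global component within a scan
#'   (arousal-like nonstationarity); gives all edges a shared, genuinely
#'   subject-specific component of windowed-correlation variability.  0
#'   keeps the global amplitude constant within scan.
#' @param noise_sd Overall signal scale (> 0).  Node signals are generated
#'   with unit variance (private noise absorbs the complement of the planted
#'   coupling and global variance shares) and multiplied by this scale, so
#'   correlation-based analyses are unaffected by it.
#' @param regime_length Samples per coupling regime.
#' @param smooth_window Length (samples) of the moving-average kernel applied
#'   to every node signal to emulate the slow, band-limited character of
#'   preprocessed BOLD; 1 disables smoothing.
#' @param ar_coef Autoregressive coefficient in [0, 0.9) of the AR(1) filter
#'   applied to every signal; together with `ar_subject_sd` it emulates the
#'   temporal autocorrelation of BOLD and its variation across subjects
#'   (vigilance, physiology), which is what makes windowed-correlation
#'   variability genuinely subject-specific.
#' @param ar_subject_sd Standard deviation of the per-subject jitter on
#'   `ar_coef` (truncated so the coefficient stays in [0, 0.9)); 0 gives every
#'   subject identical autocorrelation.
#' @param seed Integer seed; the cohort is a pure function of the
#'   configuration, so identical configurations yield bit-identical cohorts.
#'
#' @return A `dynfc_config` list.
#' @examples
#' cfg <- cohort_config(n_per_group = 4, n_nodes = 8, n_samples = 60,
#'                      regime_length = 10, seed = 1)
#' @export
cohort_config <- function(n_per_group = 20L,
                          n_nodes = 30L,
                          n_samples = 175L,
                          tr_seconds = 2,
                          dynamic_effect = 0.6,
                          static_effect = 0,
                          affected_edge_fraction = 0.03,
                          global_signal_sd = 0.5,
                          global_dynamics_sd = 0.3,
                          noise_sd = 1,
                          regime_length = 50L,
                          smooth_window = 3L,
                          ar_coef = 0.3,
                          ar_subject_sd = 0.12,
                          seed = 1L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group), n_nodes = as.integer(n_nodes),
    n_samples = as.integer(n_samples), tr_seconds = tr_seconds,
    dynamic_effect = dynamic_effect, static_effect = static_effect,
    affected_edge_fraction = affected_edge_fraction,
    global_signal_sd = global_signal_sd,
    global_dynamics_sd = global_dynamics_sd, noise_sd = noise_sd,
    regime_length = as.integer(regime_length),
    smooth_window = as.integer(smooth_window),
    ar_coef = ar_coef, ar_subject_sd = ar_subject_sd, seed = as.integer(seed)
  )
  if (cfg$n_per_group < 1L)
    abort("`n_per_group` must be a positive count.", class = "dynfc_invalid_config")
  if (cfg$n_nodes < 2L)
    abort("`n_nodes` must be at least 2.", class = "dynfc_invalid_config")
  if (cfg$n_samples < 2L)
    abort("`n_samples` must be a positive count >= 2.", class = "dynfc_invalid_config")
  if (cfg$tr_seconds <= 0)
    abort("`tr_seconds` must be positive.", class = "dynfc_invalid_config")
  if (cfg$dynamic_effect < 0)
    abort("`dynamic_effect` must be >= 0.", class = "dynfc_invalid_config")
  if (cfg$dynamic_effect > 0.9 || abs(cfg$static_effect) > 0.9)
    abort("planted couplings are correlations: effects must not exceed 0.9 in magnitude.",
          class = "dynfc_invalid_config")
  if (cfg$affected_edge_fraction <= 0 || cfg$affected_edge_fraction > 1)
    abort("`affected_edge_fraction` must lie in (0, 1].", class = "dynfc_invalid_config")
  if (cfg$global_signal_sd < 0)
    abort("`global_signal_sd` must be >= 0.", class = "dynfc_invalid_config")
  if (cfg$global_dynamics_sd < 0)
    abort("`global_dynamics_sd` must be >= 0.", class = "dynfc_invalid_config")
  if (cfg$noise_sd <= 0)
    abort("`noise_sd` must be > 0.", class = "dynfc_invalid_config")
  if (cfg$regime_length < 1L)
    abort("`regime_length` must be a positive count.", class = "dynfc_invalid_config")
  if (cfg$n_samples < 2L * cfg$regime_length)
    abort("`n_samples` must be at least 2 * `regime_length`.",
          class = "dynfc_invalid_config")
  if (cfg$smooth_window < 1L)
    abort("`smooth_window` must be >= 1.", class = "dynfc_invalid_config")
  if (cfg$ar_coef < 0 || cfg$ar_coef >= 0.9)
    abort("`ar_coef` must lie in [0, 0.9).", class = "dynfc_invalid_config")
  if (cfg$ar_subject_sd < 0)
    abort("`ar_subject_sd` must be >= 0.", class = "dynfc_invalid_config")
  structure(cfg, class = "dynfc_config")
}

# moving-average smoothing, columnwise, with shrinking windows at the ends so
# T is preserved and no NA appears
ma_smooth <- function(x, k) {
  if (k <= 1L) return(x)
  n <- nrow(x)
  half <- (k - 1L) %/% 2L
  y <- stats::filter(x, rep(1 / k, k), sides = 2)
  y <- matrix(as.numeric(y), nrow = n)
  edge <- which(is.na(y[, 1L]))
  for (t in edge) {
    rows <- max(1L, t - half):min(n, t + (k - 1L) - half)
    y[t, ] <- colMeans(x[rows, , drop = FALSE])
  }
  y
}

#' Simulate a two-group cohort of regional time series
#'
#' Draws `n_per_group` subjects per group from a latent-factor signal model in
#' which every node has unit variance and planted couplings are target
#' instantaneous correlations.  Each affected edge (i, j) — the affected set
#' is a node-disjoint matching drawn from `seed` — has a shared unit-variance
#' Gaussian factor.  In patients the edge's target coupling is
#' `c(t) = static_effect + dynamic_effect * s(t)`, where `s(t)` alternates
#' sign every `regime_length` samples (random starting sign per subject and
#' edge) and is mean-centered over the series; the factor enters node i with
#' loading `sqrt(|c(t)|)` and node j with loading `sign(c(t)) * sqrt(|c(t)|)`,
#' and each node's private noise variance absorbs the complement, so the
#' instantaneous correlation of the pair equals `c(t)` and node variances are
#' identical across groups (no variance signature leaks into unplanted
#' edges).  A regime-switching coupling therefore swings the windowed
#' correlation while cancelling out of the full-series mean correlation; a
#' constant coupling shifts the mean correlation only.  In controls all
#' planted couplings are zero.  An optional shared global component with
#' subject-jittered amplitude is added, every signal is moving-average
#' smoothed, and the result is scaled by `noise_sd`.  With both effects at
#' zero the two groups are exchangeable.
#'
#' @param config A [cohort_config()] object.
#' @return A `dynfc_cohort` tibble with columns `subject_id`, `group`
#'   (factor, levels `control` < `patient`) and `series` (list of T x N
#'   matrices whose columns are node ids).  The planted-edge annotation is
#'   attached as attribute `"edge_truth"` (see [edge_truth()]) and the
#'   configuration as attribute `"config"`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_per_group = 3, n_nodes = 6,
#'                                      n_samples = 60, regime_length = 10))
#' coh
#' edge_truth(coh)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "dynfc_config"))
  N <- config$n_nodes
  Tn <- config$n_samples
  pairs <- upper_pairs(N)
  E <- nrow(pairs)
  n_aff <- max(1L, round(config$affected_edge_fraction * E))

  withr::with_seed(config$seed, {
    # planted edges form a node-disjoint matching so that each planted
    # coupling can be realized exactly as the target instantaneous
    # correlation of its node pair inside a unit-variance factor model
    n_aff <- min(n_aff, N %/% 2L)
    affected <- sample_matching(pairs, n_aff)
    node_ids <- sprintf("n%03d", seq_len(N))
    n_regimes <- ceiling(Tn / config$regime_length)
    regime_of <- rep(seq_len(n_regimes), each = config$regime_length)[seq_len(Tn)]
    # largest planted |coupling| implied by the configuration (centering can
    # push the switching term slightly beyond +/- dynamic_effect)
    v_max <- min(0.95,
                 abs(config$static_effect) + config$dynamic_effect * (1 + 1 / n_regimes))

    simulate_one <- function(group) {
      # target correlation c_e(t) of each planted edge
      coupling <- matrix(0, Tn, length(affected))
      if (group == "patient") {
        for (k in seq_along(affected)) {
          start <- sample(c(-1, 1), 1L)
          signs <- start * (-1)^(seq_len(n_regimes) - 1L)
          s_t <- signs[regime_of]
          # centering keeps the switching component orthogonal to the
          # full-series mean coupling even when T is not a whole number of
          # balanced regimes
          s_t <- s_t - mean(s_t)
          coupling[, k] <- config$static_effect + config$dynamic_effect * s_t
        }
        coupling <- pmin(pmax(coupling, -0.95), 0.95)
      }
      # subject-to-subject variation in global fluctuation amplitude is a
      # hallmark of resting-state cohorts (and the reason global-signal
      # regression changes results); log-normal with unit median.  Within the
      # scan the amplitude drifts slowly (arousal/vigilance), so windowed
      # correlations of all edges co-fluctuate — the shared component of
      # dynamic-connectivity variability.  Amplitudes are capped so every
      # node keeps non-negative private variance.  Nodes of planted pairs
      # must reserve variance for the planted factor, so their global
      # loading is capped — by a function of the configured effect sizes and
      # the config-determined planted node set only, hence identically in
      # both groups.
      a_t <- rep(0, Tn)
      if (config$global_signal_sd > 0) {
        gs <- config$global_signal_sd * exp(rnorm(1L, 0, 0.4))
        a_t <- rep(gs, Tn)
        if (config$global_dynamics_sd > 0) {
          phi_env <- 0.95
          h <- as.numeric(stats::filter(
            rnorm(Tn, 0, config$global_dynamics_sd * sqrt(1 - phi_env^2)),
            phi_env, method = "recursive"))
          a_t <- gs * exp(h - mean(h))
        }
        a_t <- pmin(a_t, 0.9)
      }
      A <- matrix(a_t, Tn, N)
      planted_nodes <- unique(c(pairs$node_i[affected], pairs$node_j[affected]))
      if (length(planted_nodes) > 0 && v_max > 0)
        A[, planted_nodes] <- pmin(A[, planted_nodes, drop = FALSE],
                                   0.9 * sqrt(max(1 - v_max, 0)))
      # private variance of node i at time t: 1 - a_i(t)^2 - |c_e(t)|
      priv_var <- 1 - A^2
      x <- matrix(0, Tn, N)
      for (k in seq_along(affected)) {
        e <- affected[k]
        i <- pairs$node_i[e]; j <- pairs$node_j[e]
        cc <- coupling[, k]
        f <- rnorm(Tn)
        # shared factor enters node i with loading sqrt(|c|), node j with
        # sign(c) sqrt(|c|): the induced instantaneous correlation is c(t)
        a <- sqrt(abs(cc))
        x[, i] <- x[, i] + a * f
        x[, j] <- x[, j] + sign(cc) * a * f
        priv_var[, i] <- priv_var[, i] - abs(cc)
        priv_var[, j] <- priv_var[, j] - abs(cc)
      }
      x <- x + sqrt(pmax(priv_var, 0)) * matrix(rnorm(Tn * N), Tn, N)
      if (any(a_t > 0)) x <- x + A * rnorm(Tn)
      phi <- config$ar_coef
      if (config$ar_subject_sd > 0)
        phi <- min(max(phi + rnorm(1L, 0, config$ar_subject_sd), 0), 0.89)
      if (phi > 0)
        x <- apply(x, 2L, function(col)
          as.numeric(stats::filter(col, phi, method = "recursive")))
      x <- config$noise_sd * ma_smooth(x, config$smooth_window)
      colnames(x) <- node_ids
      x
    }

    groups <- rep(c("control", "patient"), each = config$n_per_group)
    ids <- c(sprintf("con%03d", seq_len(config$n_per_group)),
             sprintf("pat%03d", seq_len(config$n_per_group)))
    series <- lapply(groups, simulate_one)
  })

  cohort <- tibble::tibble(
    subject_id = ids,
    group = factor(groups, levels = c("control", "patient")),
    series = series
  )
  truth <- pairs
  truth$affected <- seq_len(E) %in% affected
  attr(cohort, "edge_truth") <- truth
  attr(cohort, "config") <- config
  class(cohort) <- c("dynfc_cohort", class(cohort))
  cohort
}

#' Planted-edge ground truth of a simulated cohort
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @return Tibble with one row per edge (`node_i`, `node_j`, upper triangle,
#'   i < j, row-major order) and logical `affected`.
#' @export
edge_truth <- function(cohort) {
  truth <- attr(cohort, "edge_truth")
  if (is.null(truth))
    abort("`cohort` carries no edge ground truth; was it simulated?",
          class = "dynfc_invalid_input")
  truth
}

# draw up to n_aff edges forming a node-disjoint matching, uniformly at random
sample_matching <- function(pairs, n_aff) {
  order_ <- sample.int(nrow(pairs))
  used <- integer(0)
  picked <- integer(0)
  for (e in order_) {
    i <- pairs$node_i[e]; j <- pairs$node_j[e]
    if (!(i %in% used) && !(j %in% used)) {
      picked <- c(picked, e)
      used <- c(used, i, j)
      if (length(picked) == n_aff) break
    }
  }
  sort(picked)
}

# ordered upper-triangle pairs, row-major (i < j)
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tibble::tibble(node_i = as.integer(idx[, 1L]), node_j = as.integer(idx[, 2L]))
}
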