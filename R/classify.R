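#' Confusion-matrix performance metrics
#'
#' Accuracy = (TP + TN) / (TP + FN + TN + FP), sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP), with patients as the positive class.
#'
#' @param tp,fn,tn,fp Non-negative confusion counts.
#' @return Tibble with `accuracy`, `sensitivity`, `specificity` in \[0, 1\].
#' @examples
#' confusion_metrics(67, 4, 70, 1)  # 96.5% / 94.4% / 98.6%
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0))
    abort("confusion counts must be >= 0.", class = "dynfc_invalid_input")
  if (tp + fn == 0 || tn + fp == 0)
    abort("each class must contain at least one subject.",
          class = "dynfc_undefined_metric")
  tibble::tibble(
    accuracy = (tp + tn) / (tp + fn + tn + fp),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp)
  )
}

#' ROC curve and area under the curve
#'
#' Sensitivity vs 1 - specificity over all decision-score thresholds; the
#' area equals the Mann-Whitney U statistic normalized by n1 * n2, with tied
#' scores counted one half.
#'
#' @param scores Numeric decision scores (higher = more patient-like).
#' @param labels Group labels; values `positive_class` are the positives.
#' @param positive_class Label of the positive (patient) class.
#' @return List with `curve` (tibble `threshold`, `sensitivity`,
#'   `specificity`) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive_class = "patient") {
  labels <- as.character(labels)
  pos <- labels == positive_class
  if (!any(pos) || all(pos))
    abort("both classes must be present.", class = "dynfc_undefined_metric")
  r <- pROC::roc(response = pos, predictor = as.numeric(scores),
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  curve <- tibble::tibble(threshold = r$thresholds,
                          sensitivity = r$sensitivities,
                          specificity = r$specificities)
  list(curve = curve, auc = as.numeric(pROC::auc(r)))
}

# fit a linear max-margin classifier and return a decision function oriented
# so that positive scores mean the positive class
fit_linear_svm <- function(X, y, cost, positive_class) {
  fit <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # e1071 orients the decision value toward the first label of the pair name
  first <- strsplit(colnames(fit$decision.values), "/")[[1L]][1L]
  if (first != positive_class) { w <- -w; b <- -b }
  list(weights = w, intercept = b,
       decision = function(newx) drop(newx %*% w + b))
}

# one LOOCV pass; assumes X is the full feature matrix and y a factor.
# Returns per-fold scores and bookkeeping.  `sel_all` carries the single
# selection used in non-nested mode.
loocv_core <- function(X, y, cost, threshold, nested, positive_class,
                       warn_empty = TRUE) {
  n <- nrow(X)
  pos <- y == positive_class
  scores <- numeric(n)
  fold_sel <- vector("list", n)
  fold_w <- vector("list", n)
  empty_folds <- 0L

  sel_all <- NULL
  if (!nested) {
    res <- t_stat_matrix(X[pos, , drop = FALSE], X[!pos, , drop = FALSE])
    sel_all <- which(res$p < threshold)
    if (length(sel_all) == 0L) { sel_all <- seq_len(ncol(X)); empty_folds <- NA_integer_ }
  }

  for (s in seq_len(n)) {
    tr <- setdiff(seq_len(n), s)
    ytr <- y[tr]
    if (length(unique(ytr)) < 2L)
      abort("a fold's training set lost a class.", class = "dynfc_invalid_design")
    if (nested) {
      Xtr <- X[tr, , drop = FALSE]
      ptr <- pos[tr]
      res <- t_stat_matrix(Xtr[ptr, , drop = FALSE], Xtr[!ptr, , drop = FALSE])
      sel <- which(res$p < threshold)
      if (length(sel) == 0L) { sel <- seq_len(ncol(X)); empty_folds <- empty_folds + 1L }
    } else {
      sel <- sel_all
    }
    fit <- fit_linear_svm(X[tr, sel, drop = FALSE], droplevels(ytr), cost,
                          positive_class)
    scores[s] <- fit$decision(X[s, sel, drop = FALSE])
    fold_sel[[s]] <- sel
    fold_w[[s]] <- setNames(fit$weights, colnames(X)[sel])
  }
  if (warn_empty && !is.na(empty_folds) && empty_folds > 0L)
    warn(sprintf("%d fold(s) selected no feature; fell back to all features.",
                 empty_folds), class = "dynfc_empty_selection")
  # score exactly 0 is assigned to the negative (control) class
  predicted <- ifelse(scores > 0, positive_class,
                      setdiff(levels(y), positive_class))
  list(scores = scores, predicted = predicted, fold_sel = fold_sel,
       fold_w = fold_w)
}

#' Leave-one-out cross-validated linear-margin classification
#'
#' Each subject is held out in turn; on the remaining subjects the edge
#' filter ([select_edge_features()]) and a linear support-vector machine
#' (penalty `cost`) are fit, and the held-out subject's decision score is
#' recorded.  With `nested = TRUE` (default) feature selection is recomputed
#' inside every fold from training rows only, so no information about the
#' held-out subject leaks into the model; `nested = FALSE` reproduces the
#' alternative protocol that selects once on the full sample before
#' cross-validation.
#'
#' @param features A `dynfc_features` tibble from [edge_features()].
#' @param cost SVM penalty C (> 0).
#' @param selection_threshold p-value threshold of the univariate edge filter.
#' @param nested Recompute selection within every fold (recommended).
#' @param positive_class Label scored as positive (patient).
#' @return A `dynfc_loocv` object: per-fold predictions and scores
#'   (`$folds`), confusion counts (`$confusion`), `$metrics`
#'   (accuracy/sensitivity/specificity), pooled `$roc` curve and `$auc`, and
#'   per-fold selections and weights for leakage checks and weight-consensus
#'   anatomy.  Use [tidy()] / [glance()] to extract tibbles.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_per_group = 5, n_nodes = 8,
#'                                      n_samples = 60, regime_length = 10,
#'                                      dynamic_effect = 0, static_effect = 2))
#' f <- edge_features(compute_connectivity(coh, "static"))
#' glance(classify_loocv(f))
#' @export
classify_loocv <- function(features, cost = 1, selection_threshold = 0.01,
                           nested = TRUE, positive_class = "patient") {
  if (cost <= 0)
    abort("`cost` must be > 0.", class = "dynfc_invalid_input")
  if (selection_threshold <= 0 || selection_threshold > 1)
    abort("`selection_threshold` must lie in (0, 1].",
          class = "dynfc_invalid_input")
  y <- droplevels(factor(features$group))
  if (any(table(y) < 2L) || nlevels(y) != 2L)
    abort("need two classes with at least 2 subjects each.",
          class = "dynfc_invalid_design")
  if (!positive_class %in% levels(y))
    abort("`positive_class` not present in `group`.",
          class = "dynfc_invalid_design")
  X <- features_matrix(features)

  core <- loocv_core(X, y, cost, selection_threshold, nested, positive_class)

  truth <- as.character(y)
  tp <- sum(core$predicted == positive_class & truth == positive_class)
  fn <- sum(core$predicted != positive_class & truth == positive_class)
  tn <- sum(core$predicted != positive_class & truth != positive_class)
  fp <- sum(core$predicted == positive_class & truth != positive_class)
  roc <- roc_auc(core$scores, truth, positive_class)

  structure(list(
    folds = tibble::tibble(subject_id = features$subject_id, group = truth,
                           score = core$scores, predicted = core$predicted),
    confusion = tibble::tibble(tp = tp, fn = fn, tn = tn, fp = fp),
    metrics = confusion_metrics(tp, fn, tn, fp),
    roc = roc$curve, auc = roc$auc,
    fold_selection = core$fold_sel, fold_weights = core$fold_w,
    config = list(cost = cost, selection_threshold = selection_threshold,
                  nested = nested, positive_class = positive_class),
    kind = attr(features, "kind"),
    permutation = NULL
  ), class = "dynfc_loocv")
}

#' @export
print.dynfc_loocv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "Leave-one-out linear-margin classification (%s connectivity)\n",
    x$kind %||% "unspecified"))
  cat(sprintf("  %d subjects; nested selection: %s; C = %g; p < %g filter\n",
              nrow(x$folds), x$config$nested, x$config$cost,
              x$config$selection_threshold))
  cat(sprintf("  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%  AUC %.4f\n",
              100 * m$accuracy, 100 * m$sensitivity, 100 * m$specificity, x$auc))
  if (!is.null(x$permutation))
    cat(sprintf("  permutation p = %.4g (%d permutations, %s estimator)\n",
                x$permutation$p, x$permutation$n_permutations,
                x$permutation$estimator))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label-permutation test of classification accuracy
#'
#' Builds the null distribution of LOOCV accuracy by shuffling all subject
#' labels and rerunning the complete pipeline — including per-fold feature
#' selection when nested — for each permutation.  The default p-value is the
#' +1-corrected estimator (1 + #\{null >= observed\}) / (B + 1), which can
#' never be exactly 0; `estimator = "proportion"` gives the plain proportion
#' of null accuracies strictly greater than the observed one (floor 0, so
#' with B = 5000 a never-exceeded accuracy reports p < 1/5000 = 0.0002).
#'
#' @inheritParams classify_loocv
#' @param report A `dynfc_loocv` fit of the same features; supplies the
#'   observed accuracy and the classifier settings.
#' @param n_permutations Number B of label permutations.
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @param estimator `"corrected"` or `"proportion"` (see Details).
#' @return The `report` with a `$permutation` element added: `p`,
#'   `null_accuracy` (length B), `n_permutations`, `estimator`, `seed`.
#' @export
permutation_test <- function(features, report, n_permutations = 5000L,
                             seed = 1L, estimator = c("corrected", "proportion")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(report, "dynfc_loocv"))
  if (n_permutations < 1L)
    abort("`n_permutations` must be >= 1.", class = "dynfc_invalid_input")
  observed <- report$metrics$accuracy
  if (observed < 0 || observed > 1)
    abort("observed accuracy must lie in [0, 1].", class = "dynfc_invalid_input")
  y <- droplevels(factor(features$group))
  X <- features_matrix(features)
  cfg <- report$config

  null_acc <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      yp <- sample(y)
      core <- suppressWarnings(
        loocv_core(X, yp, cfg$cost, cfg$selection_threshold, cfg$nested,
                   cfg$positive_class, warn_empty = FALSE))
      mean(core$predicted == as.character(yp))
    }, numeric(1L))
  })

  p <- switch(estimator,
    corrected = (1 + sum(null_acc >= observed)) / (n_permutations + 1),
    proportion = sum(null_acc > observed) / n_permutations
  )
  report$permutation <- list(p = p, null_accuracy = null_acc,
                             n_permutations = as.integer(n_permutations),
                             estimator = estimator, seed = as.integer(seed))
  report
}
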